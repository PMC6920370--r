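## Inheritance-mode segregation filters, cross-family control exclusion,
## and the misclassification-tolerant relabeling search.
##
## Missing-genotype policy: a missing call never violates a predicate, but a
## variant supported only by missing calls in the affecteds fails.

.famContext <- function(ped, labels, samples) {
  m <- ped@members
  if (is.null(labels)) labels <- affectionLabels(ped)
  seqIn <- m$id[m$sequenced & m$id %in% samples]
  aff <- seqIn[labels[seqIn] == "affected"]
  unaff <- seqIn[labels[seqIn] == "unaffected"]
  sex <- setNames(m$sex, m$id)
  fa <- setNames(m$fatherId, m$id)
  mo <- setNames(m$motherId, m$id)
  info <- aff[!is.na(fa[aff]) & fa[aff] %in% seqIn &
                !is.na(mo[aff]) & mo[aff] %in% seqIn]
  parentsOfAff <- unique(c(fa[aff], mo[aff]))
  parentsOfAff <- parentsOfAff[!is.na(parentsOfAff) & parentsOfAff %in% seqIn]
  list(labels = labels, seq = seqIn, aff = aff, unaff = unaff, sex = sex,
       father = fa, mother = mo, trioAff = info,
       parentsOfAff = parentsOfAff)
}

.sub <- function(G, ids) G[, ids, drop = FALSE]
.noneViolate <- function(G, ids, bad) {
  if (!length(ids)) return(rep(TRUE, nrow(G)))
  g <- .sub(G, ids)
  rowSums(!is.na(g) & bad(g)) == 0
}
.someObserved <- function(G, ids, good) {
  if (!length(ids)) return(rep(FALSE, nrow(G)))
  g <- .sub(G, ids)
  rowSums(!is.na(g) & good(g)) > 0
}

.dominantVec <- function(G, ctx) {
  .noneViolate(G, ctx$aff, function(g) g == 0) &
    .someObserved(G, ctx$aff, function(g) g >= 1) &
    .noneViolate(G, ctx$unaff, function(g) g >= 1)
}

.recessiveHomVec <- function(G, ctx) {
  .noneViolate(G, ctx$aff, function(g) g < 2) &
    .someObserved(G, ctx$aff, function(g) g == 2) &
    .noneViolate(G, ctx$unaff, function(g) g == 2) &
    .noneViolate(G, ctx$parentsOfAff, function(g) g == 0)
}

.xLinkedVec <- function(G, ctx) {
  affM <- ctx$aff[ctx$sex[ctx$aff] == "male"]
  affF <- ctx$aff[ctx$sex[ctx$aff] == "female"]
  unM <- ctx$unaff[ctx$sex[ctx$unaff] == "male"]
  unF <- ctx$unaff[ctx$sex[ctx$unaff] == "female"]
  .noneViolate(G, affM, function(g) g == 0) &
    .noneViolate(G, affF, function(g) g < 2) &
    .noneViolate(G, unM, function(g) g >= 1) &
    .noneViolate(G, unF, function(g) g == 2) &
    (.someObserved(G, affM, function(g) g >= 1) |
       .someObserved(G, affF, function(g) g == 2))
}

.deNovoVec <- function(G, ctx) {
  par <- unique(c(ctx$father[ctx$trioAff], ctx$mother[ctx$trioAff]))
  .noneViolate(G, ctx$trioAff, function(g) g == 0) &
    .someObserved(G, ctx$trioAff, function(g) g >= 1) &
    .noneViolate(G, par, function(g) g >= 1) &
    .noneViolate(G, ctx$unaff, function(g) g >= 1)
}

.asGenoMatrix <- function(geno) {
  if (is.matrix(geno)) geno
  else matrix(geno, 1, dimnames = list(NULL, names(geno)))
}

#' Dominant segregation predicate
#'
#' TRUE iff every sequenced affected member carries at least one alt allele
#' and no sequenced unaffected member carries any. Unknown-affection members
#' are unconstrained; missing calls never violate, but at least one affected
#' must have an observed carrier genotype.
#'
#' @param geno named alt-dosage vector (sample id -> 0/1/2/NA).
#' @param ped a \linkS4class{Pedigree}.
#' @param labels optional named affection vector overriding the pedigree's.
#' @return logical.
#' @export
fitsDominant <- function(geno, ped, labels = NULL) {
  G <- .asGenoMatrix(geno)
  .dominantVec(G, .famContext(ped, labels, colnames(G)))
}

#' Recessive-homozygous segregation predicate
#'
#' TRUE iff every sequenced affected is homozygous alt, no sequenced
#' unaffected is homozygous alt, and every sequenced parent of an affected
#' carries at least one alt allele.
#'
#' @inheritParams fitsDominant
#' @return logical.
#' @export
fitsRecessiveHom <- function(geno, ped, labels = NULL) {
  G <- .asGenoMatrix(geno)
  .recessiveHomVec(G, .famContext(ped, labels, colnames(G)))
}

#' X-linked recessive segregation predicate
#'
#' For a variant on the X chromosome: every sequenced affected male carries
#' alt (hemizygotes may be coded 0/1 or 1/1), every sequenced affected
#' female is homozygous alt, no sequenced unaffected male carries alt, and
#' no sequenced unaffected female is homozygous alt.
#'
#' @inheritParams fitsDominant
#' @return logical.
#' @export
fitsXLinked <- function(geno, ped, labels = NULL) {
  G <- .asGenoMatrix(geno)
  .xLinkedVec(G, .famContext(ped, labels, colnames(G)))
}

#' De novo segregation predicate
#'
#' Over the affecteds that have both parents sequenced (at least one such is
#' required): each carries alt, both its parents carry none, and no
#' sequenced unaffected anywhere in the family carries alt (extended
#' relatives act as controls, stricter than minimal trio logic).
#'
#' @inheritParams fitsDominant
#' @return logical.
#' @export
fitsDeNovo <- function(geno, ped, labels = NULL) {
  G <- .asGenoMatrix(geno)
  ctx <- .famContext(ped, labels, colnames(G))
  if (!length(ctx$trioAff))
    stop("de novo filter requires at least one affected with both parents sequenced")
  .deNovoVec(G, ctx)
}

#' Compound-heterozygote pair search within one gene
#'
#' Returns variant pairs (a, b) such that every sequenced affected is
#' heterozygous for both; when at least one affected has both parents
#' sequenced, the pair must be phase-consistent with trans inheritance (one
#' variant transmissible from each parent); without parental data pairs are
#' returned flagged \code{phaseUnknown}. No sequenced unaffected may carry
#' both members of a pair.
#'
#' @param geno dosage matrix (variants x samples) with variant keys as
#'   rownames; all variants must be annotated to the same gene.
#' @param ped a \linkS4class{Pedigree}.
#' @param labels optional named affection vector.
#' @return data.frame with columns \code{key1}, \code{key2},
#'   \code{phaseUnknown} (zero rows when no pair qualifies).
#' @export
fitsCompoundHet <- function(geno, ped, labels = NULL) {
  G <- .asGenoMatrix(geno)
  ctx <- .famContext(ped, labels, colnames(G))
  empty <- data.frame(key1 = character(), key2 = character(),
                      phaseUnknown = logical(), stringsAsFactors = FALSE)
  het <- .noneViolate(G, ctx$aff, function(g) g != 1) &
    .someObserved(G, ctx$aff, function(g) g == 1)
  cand <- which(het)
  if (length(cand) < 2) return(empty)
  keys <- rownames(G)
  phaseUnknown <- length(ctx$trioAff) == 0
  pairs <- combn(cand, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    # no sequenced unaffected carries both
    if (length(ctx$unaff)) {
      ga <- G[a, ctx$unaff]; gb <- G[b, ctx$unaff]
      if (any(!is.na(ga) & ga >= 1 & !is.na(gb) & gb >= 1)) return(NULL)
    }
    if (!phaseUnknown) {
      for (child in ctx$trioAff) {
        fa <- ctx$father[child]; mo <- ctx$mother[child]
        pf <- function(i) is.na(G[i, fa]) || G[i, fa] >= 1
        pm <- function(i) is.na(G[i, mo]) || G[i, mo] >= 1
        if (!((pf(a) && pm(b)) || (pm(a) && pf(b)))) return(NULL)
      }
    }
    data.frame(key1 = keys[a], key2 = keys[b], phaseUnknown = phaseUnknown,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Cross-family control exclusion
#'
#' Under the rare-disease rare-variant hypothesis, every sequenced subject
#' outside the target family is a healthy control: a variant carried by any
#' of them is removed. Missing calls never trigger removal.
#'
#' @param geno named dosage vector over all cohort samples.
#' @param sampleFamily named character vector sample -> family id.
#' @param family target family id.
#' @return \code{"remove"} or \code{"keep"}.
#' @export
crossFamilyExclude <- function(geno, sampleFamily, family) {
  keep <- .crossFamKeep(.asGenoMatrix(geno), sampleFamily, family)
  if (keep) "keep" else "remove"
}

.crossFamKeep <- function(G, sampleFamily, family) {
  others <- names(sampleFamily)[sampleFamily != family]
  others <- intersect(others, colnames(G))
  if (!length(others)) return(rep(TRUE, nrow(G)))
  g <- .sub(G, others)
  rowSums(!is.na(g) & g >= 1) == 0
}

#' Models a pedigree can support
#'
#' Dominant, recessive-homozygous and compound-het always apply; X-linked
#' when some sequenced affected is male; de novo when some sequenced
#' affected has both parents sequenced.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @return character vector of model names.
#' @export
compatibleModels <- function(ped) {
  ctx <- .famContext(ped, NULL, sequencedIds(ped))
  models <- c("dominant", "recessive_hom", "compound_het")
  if (any(ctx$sex[ctx$aff] == "male")) models <- c(models, "x_linked")
  if (length(ctx$trioAff)) models <- c(models, "de_novo")
  models
}

.runCht <- function(G, ped, ctx, geneOf) {
  out <- data.frame(key1 = character(), key2 = character(), gene = character(),
                    phaseUnknown = logical(), stringsAsFactors = FALSE)
  if (is.null(geneOf)) return(out)
  het <- .noneViolate(G, ctx$aff, function(g) g != 1) &
    .someObserved(G, ctx$aff, function(g) g == 1)
  genes <- unique(geneOf[het & !is.na(geneOf)])
  for (gn in genes) {
    idx <- which(geneOf == gn & het)
    if (length(idx) < 2) next
    sub <- G[idx, , drop = FALSE]
    pr <- fitsCompoundHet(sub, ped, labels = ctx$labels)
    if (nrow(pr)) {
      pr$gene <- gn
      out <- rbind(out, pr[, c("key1", "key2", "gene", "phaseUnknown")])
    }
  }
  out
}

#' Run segregation filtering for one family
#'
#' Applies cross-family control exclusion, then each requested
#' inheritance-model predicate, under the given affection labels.
#'
#' @param cohort a \linkS4class{GenotypeCohort} with sample-family mapping
#'   attached (see \code{\link{setSampleFamilies}}).
#' @param ped the target family's \linkS4class{Pedigree}.
#' @param models model names (default \code{\link{compatibleModels}}).
#' @param labels optional named affection vector overriding the pedigree's.
#' @param annotations annotation data.frame (needed for compound-het gene
#'   grouping; others run without it).
#' @param xChrom chromosome name treated as X.
#' @param crossFamily apply cross-family exclusion (default TRUE).
#' @return list with \code{results} (per model: data.frame of retained
#'   variants; for compound_het one row per qualifying pair) and
#'   \code{counts} (named integer: variants retained per model).
#' @export
runSegregation <- function(cohort, ped, models = NULL, labels = NULL,
                           annotations = NULL, xChrom = "chrX",
                           crossFamily = TRUE) {
  if (is.null(models)) models <- compatibleModels(ped)
  stopifnot(all(models %in% .MODELS))
  samples <- intersect(sequencedIds(ped), cohortSamples(cohort))
  ctx <- .famContext(ped, labels, samples)
  if (!length(ctx$aff))
    stop(sprintf("family %s has no sequenced affected member", familyId(ped)))
  if ("de_novo" %in% models && !length(ctx$trioAff))
    stop("configuration error: de_novo requested but no affected has both parents sequenced")
  v <- cohort@variants
  Gfam <- cohort@geno[, ctx$seq, drop = FALSE]
  keep <- if (crossFamily)
    .crossFamKeep(cohort@geno, cohort@sampleFamily, familyId(ped))
  else rep(TRUE, nrow(v))
  isX <- v$chrom == xChrom
  geneOf <- NULL
  if (!is.null(annotations))
    geneOf <- alignAnnotations(annotations, v$key)$gene
  results <- list()
  counts <- integer()
  for (mod in models) {
    if (mod == "compound_het") {
      sel <- which(keep)
      sub <- Gfam[sel, , drop = FALSE]
      rownames(sub) <- v$key[sel]
      pr <- .runCht(sub, ped, ctx, if (is.null(geneOf)) NULL else geneOf[sel])
      results[[mod]] <- pr
      counts[mod] <- length(unique(c(pr$key1, pr$key2)))
    } else {
      pass <- switch(mod,
        dominant = .dominantVec(Gfam, ctx),
        recessive_hom = .recessiveHomVec(Gfam, ctx),
        x_linked = .xLinkedVec(Gfam, ctx) & isX,
        de_novo = .deNovoVec(Gfam, ctx))
      sel <- which(pass & keep)
      results[[mod]] <- v[sel, c("key", "chrom", "pos", "ref", "alt")]
      rownames(results[[mod]]) <- NULL
      counts[mod] <- length(sel)
    }
  }
  list(results = results, counts = counts)
}

#' Misclassification-tolerant relabeling search
#'
#' Re-runs the segregation cascade under every affection-label assignment
#' with up to \code{maxFlips} flips of soft-labeled sequenced members, in
#' ascending flip-count order, and reports each surviving candidate once at
#' the minimal flip count at which it first appears, together with every
#' flip set producing it at that count. Downstream annotation filters
#' (database/frequency and predictor vote) are applied before reporting so
#' the search only tracks reportable candidates.
#'
#' @inheritParams runSegregation
#' @param maxFlips maximum number of label flips.
#' @param rule frequency rule for the annotation filters.
#' @param dbPolicy database filter policy ("default" or "strict").
#' @param applyAnnotationFilters set FALSE to search on segregation alone.
#' @param cap refuse when the number of assignments exceeds this guard.
#' @return data.frame ranked by (minimal flips, number of flip sets,
#'   coordinate) with columns \code{key}, \code{chrom}, \code{pos},
#'   \code{gene}, \code{funcClass}, \code{models}, \code{partner},
#'   \code{minFlips}, \code{nFlipSets} and list-column \code{flipSets}.
#' @export
misclassificationSearch <- function(cohort, ped, annotations = NULL,
                                    models = NULL, maxFlips = 0,
                                    rule = defaultFreqRule(),
                                    dbPolicy = "default", xChrom = "chrX",
                                    applyAnnotationFilters = TRUE,
                                    cap = 1e5) {
  if (maxFlips < 0) stop("maxFlips must be nonnegative")
  nAssign <- countRelabelings(ped, maxFlips)
  if (nAssign > cap)
    stop(sprintf("relabeling space too large (%s assignments > cap %s)",
                 format(nAssign), format(cap)))
  if (is.null(models)) models <- compatibleModels(ped)
  v <- cohort@variants
  ann <- if (is.null(annotations)) NULL else alignAnnotations(annotations, v$key)
  pre <- .crossFamKeep(cohort@geno, cohort@sampleFamily, familyId(ped))
  if (applyAnnotationFilters && !is.null(ann))
    pre <- pre & !.dbRemove(ann, rule, dbPolicy) & .voteDeleterious(ann)
  sub <- cohort
  sub@variants <- v[pre, , drop = FALSE]
  sub@geno <- cohort@geno[pre, , drop = FALSE]
  if (!is.null(sub@gq)) sub@gq <- sub@gq[pre, , drop = FALSE]

  seen <- new.env(parent = emptyenv())
  assignments <- enumerateRelabelings(ped, maxFlips)
  for (as_ in assignments) {
    k <- as_$flipCount
    # an assignment can void a model's precondition (e.g. no affected with
    # sequenced parents left for de novo); such models simply yield nothing
    ctxA <- .famContext(ped, as_$labels,
                        intersect(sequencedIds(ped), cohortSamples(sub)))
    modelsA <- models
    if (!length(ctxA$aff)) next
    if ("de_novo" %in% modelsA && !length(ctxA$trioAff))
      modelsA <- setdiff(modelsA, "de_novo")
    if (!length(modelsA)) next
    res <- runSegregation(sub, ped, models = modelsA, labels = as_$labels,
                          annotations = ann, xChrom = xChrom,
                          crossFamily = FALSE)
    hits <- list()
    for (mod in names(res$results)) {
      r <- res$results[[mod]]
      if (!nrow(r)) next
      if (mod == "compound_het") {
        for (i in seq_len(nrow(r))) {
          hits[[length(hits) + 1]] <- list(key = r$key1[i], mod = mod,
                                           partner = r$key2[i])
          hits[[length(hits) + 1]] <- list(key = r$key2[i], mod = mod,
                                           partner = r$key1[i])
        }
      } else {
        for (key in r$key)
          hits[[length(hits) + 1]] <- list(key = key, mod = mod,
                                           partner = NA_character_)
      }
    }
    for (h in hits) {
      rec <- if (exists(h$key, seen)) get(h$key, seen) else
        list(minK = k, models = character(), flipSets = list(),
             partner = NA_character_)
      if (rec$minK < k) next      # already reported at a smaller flip count
      rec$models <- union(rec$models, h$mod)
      if (!is.na(h$partner)) rec$partner <- h$partner
      sig <- paste(sort(as_$flippedIds), collapse = "+")
      if (!sig %in% vapply(rec$flipSets, function(x)
        paste(sort(x), collapse = "+"), "")) {
        rec$flipSets <- c(rec$flipSets, list(as_$flippedIds))
      }
      assign(h$key, rec, seen)
    }
  }
  keys <- ls(seen)
  if (!length(keys))
    return(data.frame(key = character(), chrom = character(), pos = numeric(),
                      gene = character(), funcClass = character(),
                      models = character(), partner = character(),
                      minFlips = integer(), nFlipSets = integer(),
                      stringsAsFactors = FALSE))
  recs <- lapply(keys, get, envir = seen)
  idx <- match(keys, v$key)
  out <- data.frame(
    key = keys, chrom = v$chrom[idx], pos = v$pos[idx],
    gene = if (is.null(ann)) NA_character_ else ann$gene[match(keys, ann$key)],
    funcClass = if (is.null(ann)) NA_character_ else
      ann$funcClass[match(keys, ann$key)],
    models = vapply(recs, function(r) paste(sort(r$models), collapse = ","), ""),
    partner = vapply(recs, function(r) r$partner, ""),
    minFlips = vapply(recs, function(r) as.integer(r$minK), 1L),
    nFlipSets = vapply(recs, function(r) length(r$flipSets), 1L),
    stringsAsFactors = FALSE)
  out$flipSets <- lapply(recs, function(r) r$flipSets)
  ord <- order(out$minFlips, out$nFlipSets, out$chrom, out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "assignmentsTested") <- length(assignments)
  out
}
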