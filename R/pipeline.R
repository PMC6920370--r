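## Full per-family analysis: segregation + cross-family exclusion, then the
## database/frequency filter, then the predictor consensus vote, with a
## stage trace per inheritance model and a ranked candidate report.

.traceRow <- function(family, model, flips, c1, c2, c3) {
  if (c2 > c1 || c3 > c2)
    stop("internal error: filter trace counts increased across stages")
  data.frame(family = family, model = model, flips = flips,
             postSegregation = c1, postDatabase = c2, postPrediction = c3,
             stringsAsFactors = FALSE)
}

#' Run the full filtering cascade for one family
#'
#' Stages, in order: (1) inheritance-model segregation with every sequenced
#' subject outside the family treated as a healthy control; (2) removal of
#' polymorphism-database variants via the multi-population frequency rule
#' and ESP; (3) retention of predicted-deleterious variants by the
#' consensus vote. With \code{maxFlips > 0} the misclassification-tolerant
#' relabeling search wraps the whole cascade and candidates carry the
#' minimal flip count at which they first appear. Setting
#' \code{stageOrder = "frequency_first"} applies stage 2 before stage 1;
#' the final candidate set is identical (the filters commute as set
#' intersections) but the trace then reports the cheaper order.
#'
#' @param cohort a \linkS4class{GenotypeCohort} with families attached.
#' @param pedigrees named list of \linkS4class{Pedigree}.
#' @param familyId target family id.
#' @param annotations annotation data.frame.
#' @param models inheritance models (default \code{\link{compatibleModels}}).
#' @param maxFlips maximum affection-label flips for the relabeling search.
#' @param rule frequency rule (see \code{\link{defaultFreqRule}}).
#' @param dbPolicy database filter policy.
#' @param xChrom chromosome treated as X.
#' @param stageOrder \code{"segregation_first"} (default) or
#'   \code{"frequency_first"}.
#' @return list with \code{trace} (per-model stage counts; the flip-0
#'   assignment when searching) and \code{report} (ranked candidates:
#'   \code{key}, \code{gene}, \code{funcClass}, \code{models},
#'   \code{partner}, \code{minFlips}, \code{nFlipSets}, \code{flipSets}).
#' @export
runFamilyAnalysis <- function(cohort, pedigrees, familyId, annotations,
                              models = NULL, maxFlips = 0,
                              rule = defaultFreqRule(),
                              dbPolicy = "default", xChrom = "chrX",
                              stageOrder = c("segregation_first",
                                             "frequency_first")) {
  stageOrder <- match.arg(stageOrder)
  if (!familyId %in% names(pedigrees))
    stop(sprintf("family '%s' not found in pedigrees", familyId))
  ped <- pedigrees[[familyId]]
  if (!any(pedMembers(ped)$affection == "affected" & pedMembers(ped)$sequenced))
    stop(sprintf("family '%s' has no sequenced affected member", familyId))
  if (is.null(models)) models <- compatibleModels(ped)
  if (!length(cohort@sampleFamily))
    cohort <- setSampleFamilies(cohort, pedigrees)
  v <- cohort@variants
  ann <- alignAnnotations(annotations, v$key)
  dbKeep <- !.dbRemove(ann, rule, dbPolicy)
  delet <- .voteDeleterious(ann)

  work <- cohort
  if (stageOrder == "frequency_first") {
    work@variants <- v[dbKeep, , drop = FALSE]
    work@geno <- cohort@geno[dbKeep, , drop = FALSE]
  }
  seg <- runSegregation(work, ped, models = models, annotations = ann,
                        xChrom = xChrom)
  trace <- do.call(rbind, lapply(models, function(mod) {
    r <- seg$results[[mod]]
    keys <- if (mod == "compound_het") unique(c(r$key1, r$key2)) else r$key
    i <- match(keys, ann$key)
    k2 <- keys[dbKeep[i]]
    k3 <- keys[dbKeep[i] & delet[i]]
    if (stageOrder == "frequency_first") {
      # counts reported in executed order: db filter already applied
      .traceRow(familyId, mod, 0L, length(keys), length(keys), length(k3))
    } else {
      .traceRow(familyId, mod, 0L, length(keys), length(k2), length(k3))
    }
  }))

  if (maxFlips > 0) {
    report <- misclassificationSearch(cohort, ped, annotations = ann,
                                      models = models, maxFlips = maxFlips,
                                      rule = rule, dbPolicy = dbPolicy,
                                      xChrom = xChrom)
  } else {
    rows <- list()
    for (mod in models) {
      r <- seg$results[[mod]]
      if (mod == "compound_het") {
        if (nrow(r)) for (i in seq_len(nrow(r))) {
          rows[[length(rows) + 1]] <- data.frame(
            key = c(r$key1[i], r$key2[i]), model = mod,
            partner = c(r$key2[i], r$key1[i]), stringsAsFactors = FALSE)
        }
      } else if (nrow(r)) {
        rows[[length(rows) + 1]] <- data.frame(
          key = r$key, model = mod, partner = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) {
      flat <- do.call(rbind, rows)
      i <- match(flat$key, ann$key)
      flat <- flat[dbKeep[i] & delet[i], , drop = FALSE]
      if (nrow(flat)) {
        agg <- split(flat, flat$key)
        keys <- names(agg)
        i <- match(keys, ann$key)
        report <- data.frame(
          key = keys, chrom = ann$chrom[i], pos = ann$pos[i],
          gene = ann$gene[i], funcClass = ann$funcClass[i],
          models = vapply(agg, function(d)
            paste(sort(unique(d$model)), collapse = ","), ""),
          partner = vapply(agg, function(d) {
            p <- d$partner[!is.na(d$partner)]
            if (length(p)) p[1] else NA_character_
          }, ""),
          minFlips = 0L, nFlipSets = 0L, stringsAsFactors = FALSE)
        report$flipSets <- rep(list(list()), nrow(report))
        vi <- match(report$key, v$key)
        report$chrom <- v$chrom[vi]; report$pos <- v$pos[vi]
        ord <- order(report$minFlips, report$nFlipSets, report$chrom,
                     report$pos)
        report <- report[ord, , drop = FALSE]
        rownames(report) <- NULL
      } else report <- .emptyReport()
    } else report <- .emptyReport()
  }
  list(trace = trace, report = report)
}

.emptyReport <- function() {
  r <- data.frame(key = character(), chrom = character(), pos = numeric(),
                  gene = character(), funcClass = character(),
                  models = character(), partner = character(),
                  minFlips = integer(), nFlipSets = integer(),
                  stringsAsFactors = FALSE)
  r$flipSets <- list()
  r
}

#' Variants co-segregating with disease after database filtering
#'
#' The stage-1 + stage-2 survivor set for one family under one model: the
#' input the variant-density scan consumes when hunting hidden
#' repeat-expansion loci (the predictor vote is deliberately not applied —
#' linkage-block passengers are typically silent).
#'
#' @inheritParams runFamilyAnalysis
#' @param model single inheritance model (default dominant).
#' @return data.frame of surviving variants (\code{key}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}).
#' @export
coSegregatingVariants <- function(cohort, pedigrees, familyId, annotations,
                                  model = "dominant",
                                  rule = defaultFreqRule(),
                                  dbPolicy = "default", xChrom = "chrX") {
  ped <- pedigrees[[familyId]]
  if (!length(cohort@sampleFamily))
    cohort <- setSampleFamilies(cohort, pedigrees)
  seg <- runSegregation(cohort, ped, models = model, xChrom = xChrom)
  r <- seg$results[[model]]
  ann <- alignAnnotations(annotations, r$key)
  r[!.dbRemove(ann, rule, dbPolicy), , drop = FALSE]
}

#' Write a candidate report and stage trace
#'
#' TSV (one row per candidate, stable column order; flip sets are
#' semicolon-separated, ids within a set joined by '+') and/or JSON
#' (schema-versioned, report plus trace) representations.
#'
#' @param result list from \code{\link{runFamilyAnalysis}}.
#' @param dir output directory.
#' @param format subset of \code{c("tsv", "json")}.
#' @return named vector of written paths, invisibly.
#' @export
writeReport <- function(result, dir, format = c("tsv", "json")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  rep <- result$report
  flat <- rep[, setdiff(names(rep), "flipSets"), drop = FALSE]
  flat$flipSets <- vapply(rep$flipSets, function(fs)
    paste(vapply(fs, function(x) paste(x, collapse = "+"), ""),
          collapse = ";"), "")
  if ("tsv" %in% format) {
    p <- file.path(dir, "candidates.tsv")
    write.table(flat, p, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(result$trace, file.path(dir, "trace.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths["tsv"] <- p
  }
  if ("json" %in% format) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(list(schema = "raredx-report/1",
                              candidates = flat, trace = result$trace),
                         p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths["json"] <- p
  }
  invisible(paths)
}

#' Read back a JSON report
#' @param path path written by \code{\link{writeReport}}.
#' @return list with \code{candidates} and \code{trace} data.frames.
#' @export
readReport <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "raredx-report/1"))
    stop("unrecognized report schema")
  x
}
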