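## Seeded synthetic family cohorts with the statistical structure the
## analysis assumes: rare founder alleles under Hardy-Weinberg, Mendelian
## transmission (gene dropping), one planted causal scenario per cohort,
## optional affection-label noise, and a machine-readable truth manifest.

.seedMod <- 2147483647

#' Scenario configuration for the synthetic cohort generator
#'
#' Defaults emulate the study shape this pipeline targets: 16 families
#' totalling 79 sequenced individuals (one ten-member four-generation
#' family, three eight-sequenced three-generation families, nine quartets,
#' three trios), 20,000 decoy variants with per-super-population founder
#' frequencies (a common component and a rare tail), predictor calls that
#' are damaging with probability 0.9 for damaging-truth variants and 0.1
#' for benign-truth ones, 1\% missing calls and 0.1\% allele-dropout
#' genotype errors.
#'
#' @param scenario causal scenario to plant: one of dominant,
#'   recessive_hom, compound_het, x_linked, de_novo, ssr_ld_block,
#'   denovo_cnv.
#' @param nDecoys number of decoy variant sites.
#' @param seed master RNG seed; all substreams derive from it.
#' @param nLabelFlips affection-label errors injected into the emitted PED
#'   of the target family (truth labels stay in the manifest).
#' @param flipDirection \code{"case_to_control"} (an affected recorded
#'   unaffected) or \code{"control_to_case"}.
#' @param missingRate per-call probability of a missing genotype.
#' @param dropoutRate per-call probability that one carried alt allele is
#'   dropped (het -> hom-ref, hom-alt -> het); the residual error mode
#'   after joint calling.
#' @param predDamaging,predBenign per-tool probability of a damaging call
#'   for damaging-truth / benign-truth variants.
#' @param commonFraction fraction of decoys drawn from the common-frequency
#'   component (the rest form the rare tail).
#' @param blockVariants,blockSpan,locusJitter linkage-block scenario: number
#'   of co-segregating variants, block width (bp), and the maximum offset of
#'   the hidden locus from the block center.
#' @param cnvDecoysPerParent inherited decoy CNV segments per parent in the
#'   denovo_cnv scenario.
#' @param chromLengths genome model (named vector).
#' @param xChrom chromosome treated as X.
#' @param nBackgroundGenes size of the synthetic gene table.
#' @return classed list of settings.
#' @export
scenarioConfig <- function(scenario = c("dominant", "recessive_hom",
                                        "compound_het", "x_linked",
                                        "de_novo", "ssr_ld_block",
                                        "denovo_cnv"),
                           nDecoys = 20000, seed = 1, nLabelFlips = 0,
                           flipDirection = c("case_to_control",
                                             "control_to_case"),
                           missingRate = 0.01, dropoutRate = 0.001,
                           predDamaging = 0.9, predBenign = 0.1,
                           commonFraction = 0.5, blockVariants = 100,
                           blockSpan = 16e6, locusJitter = 2e6,
                           cnvDecoysPerParent = 5,
                           chromLengths = defaultChromLengths(),
                           xChrom = "chrX", nBackgroundGenes = 180) {
  scenario <- match.arg(scenario)
  flipDirection <- match.arg(flipDirection)
  stopifnot(nDecoys > 0, missingRate >= 0, missingRate <= 1,
            dropoutRate >= 0, dropoutRate <= 1,
            predDamaging >= 0, predDamaging <= 1,
            predBenign >= 0, predBenign <= 1, nLabelFlips >= 0)
  structure(list(scenario = scenario, nDecoys = as.integer(nDecoys),
                 seed = as.integer(seed), nLabelFlips = as.integer(nLabelFlips),
                 flipDirection = flipDirection, missingRate = missingRate,
                 dropoutRate = dropoutRate, predDamaging = predDamaging,
                 predBenign = predBenign, commonFraction = commonFraction,
                 blockVariants = as.integer(blockVariants),
                 blockSpan = blockSpan, locusJitter = locusJitter,
                 cnvDecoysPerParent = as.integer(cnvDecoysPerParent),
                 chromLengths = chromLengths, xChrom = xChrom,
                 nBackgroundGenes = as.integer(nBackgroundGenes)),
            class = "scenarioConfig")
}

.mkMembers <- function(...) {
  d <- data.frame(..., stringsAsFactors = FALSE)
  names(d) <- c("id", "fatherId", "motherId", "sex", "affection", "sequenced")
  d$labelConfidence <- "soft"
  d[, c("id", "fatherId", "motherId", "sex", "affection",
        "labelConfidence", "sequenced")]
}

## Family templates. attr "carriers" names the members (incl. unsequenced
## ancestors) that carry a dominant-type planted haplotype.
.templates <- function() {
  trio <- .mkMembers(
    id = c("fat", "mot", "c1"),
    fatherId = c(NA, NA, "fat"), motherId = c(NA, NA, "mot"),
    sex = c("male", "female", "male"),
    affection = c("unaffected", "unaffected", "affected"),
    sequenced = TRUE)
  quartet <- .mkMembers(
    id = c("fat", "mot", "s1", "s2"),
    fatherId = c(NA, NA, "fat", "fat"), motherId = c(NA, NA, "mot", "mot"),
    sex = c("male", "female", "male", "male"),
    affection = c("unaffected", "unaffected", "affected", "affected"),
    sequenced = TRUE)
  ext <- .mkMembers(
    id = c("gf", "gm", "mo", "aunt", "uncle", "fat",
           "p1", "p2", "sis", "bro"),
    fatherId = c(NA, NA, "gf", "gf", "gf", NA,
                 "fat", "fat", "fat", "fat"),
    motherId = c(NA, NA, "gm", "gm", "gm", NA,
                 "mo", "mo", "mo", "mo"),
    sex = c("male", "female", "female", "female", "male", "male",
            "female", "female", "female", "male"),
    affection = c("unaffected", "unaffected", "affected", "affected",
                  "unaffected", "unaffected", "affected", "affected",
                  "unaffected", "unaffected"),
    sequenced = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                  TRUE, TRUE, TRUE, TRUE))
  attr(ext, "carriers") <- c("gm", "mo", "aunt", "p1", "p2")
  multi <- .mkMembers(
    id = c("s0", "s0sp", "A", "Asp", "B", "Bsp", "C",
           "D", "E", "E2", "F", "G", "Dsp", "H"),
    fatherId = c(NA, NA, "s0", NA, "s0", NA, "s0",
                 "A", "A", "A", "Bsp", "Bsp", NA, "D"),
    motherId = c(NA, NA, "s0sp", NA, "s0sp", NA, "s0sp",
                 "Asp", "Asp", "Asp", "B", "B", NA, "D" ),
    sex = c("male", "female", "male", "female", "female", "male", "male",
            "male", "female", "male", "male", "female", "female", "male"),
    affection = c("affected", "unaffected", "affected", "unaffected",
                  "affected", "unaffected", "unaffected", "affected",
                  "unaffected", "unaffected", "affected", "affected",
                  "unaffected", "affected"),
    sequenced = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE,
                  TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  ## fix: D's children H: father D, mother Dsp
  multi$motherId[multi$id == "H"] <- "Dsp"
  attr(multi, "carriers") <- c("s0", "A", "B", "D", "F", "G", "H")
  list(trio = trio, quartet = quartet, ext = ext, multi = multi)
}

.familyPlan <- function() {
  data.frame(
    family = sprintf("Fam%02d", 1:16),
    template = c("multi", rep("ext", 3), rep("quartet", 9), rep("trio", 3)),
    stringsAsFactors = FALSE)
}

.instantiate <- function(template, familyId, tmpl) {
  m <- tmpl[[template]]
  carriers <- attr(m, "carriers")
  pre <- function(x) ifelse(is.na(x), NA_character_,
                            paste(familyId, x, sep = "_"))
  m$id <- pre(m$id); m$fatherId <- pre(m$fatherId); m$motherId <- pre(m$motherId)
  attr(m, "carriers") <- NULL
  list(ped = Pedigree(familyId, m),
       carriers = if (is.null(carriers)) character() else pre(carriers))
}

.topoOrder <- function(m) {
  placed <- character()
  ord <- integer()
  remaining <- seq_len(nrow(m))
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      (is.na(m$fatherId[i]) || m$fatherId[i] %in% placed) &&
        (is.na(m$motherId[i]) || m$motherId[i] %in% placed)
    }, TRUE)]
    if (!length(ready)) stop("pedigree is cyclic")
    ord <- c(ord, ready)
    placed <- c(placed, m$id[ready])
    remaining <- setdiff(remaining, ready)
  }
  ord
}

## Drop one haplotype pair per member down a pedigree.
## freq: per-site founder allele frequency; xIdx: sites on the X.
## Returns dosage matrix (sites x members). Males on X carry a duplicated
## maternal allele (hemizygote coded as a homozygous diploid call).
.dropFamily <- function(members, freq, xIdx = integer()) {
  nv <- length(freq)
  ids <- members$id
  nm <- length(ids)
  hapA <- matrix(0L, nv, nm, dimnames = list(NULL, ids))  # paternal
  hapB <- matrix(0L, nv, nm, dimnames = list(NULL, ids))  # maternal
  male <- members$sex == "male"
  for (j in .topoOrder(members)) {
    fi <- match(members$fatherId[j], ids)
    mi <- match(members$motherId[j], ids)
    if (is.na(fi)) {
      pA <- rbinom(nv, 1L, freq)
    } else {
      pick <- runif(nv) < 0.5
      pA <- hapA[, fi]
      pA[pick] <- hapB[pick, fi]
      if (length(xIdx)) pA[xIdx] <- hapB[xIdx, fi]  # father's true X
    }
    if (is.na(mi)) {
      pB <- rbinom(nv, 1L, freq)
    } else {
      pick <- runif(nv) < 0.5
      pB <- hapA[, mi]
      pB[pick] <- hapB[pick, mi]
    }
    if (male[j] && length(xIdx)) pA[xIdx] <- pB[xIdx]  # hemizygote, coded dup
    hapA[, j] <- pA
    hapB[, j] <- pB
  }
  hapA + hapB
}

#' Gene dropping: simulate genotypes at independent sites down a pedigree
#'
#' Founders draw alleles from Hardy-Weinberg at the site frequency;
#' non-founders receive one uniformly chosen allele from each parent.
#' Deterministic given the RNG state.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param freq allele frequency, either a scalar or one value per site.
#' @param n number of sites (ignored when \code{freq} has length > 1).
#' @param xLinked simulate X-chromosome transmission (males hemizygous,
#'   coded as homozygous diploid calls).
#' @return dosage matrix (sites x members), all members including
#'   unsequenced ones.
#' @export
geneDrop <- function(ped, freq, n = 1, xLinked = FALSE) {
  if (length(freq) == 1) freq <- rep(freq, n)
  .dropFamily(ped@members, freq,
              xIdx = if (xLinked) seq_along(freq) else integer())
}

#' Inject affection-label errors into a pedigree
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param flips character vector of member ids whose affected/unaffected
#'   label is toggled. Flipping a firm-labeled member is an error.
#' @return list with \code{ped} (the relabeled pedigree) and \code{flips}
#'   (data.frame id, from, to).
#' @export
injectLabelNoise <- function(ped, flips) {
  if (!length(flips))
    return(list(ped = ped, flips = data.frame(id = character(),
                                              from = character(),
                                              to = character())))
  m <- ped@members
  idx <- match(flips, m$id)
  if (anyNA(idx)) stop("unknown member id in flips")
  if (any(m$labelConfidence[idx] == "firm"))
    stop("cannot flip a firm-labeled member")
  if (any(m$affection[idx] == "unknown"))
    stop("cannot flip an unknown-affection member")
  from <- m$affection[idx]
  to <- ifelse(from == "affected", "unaffected", "affected")
  ped@members$affection[idx] <- to
  validObject(ped)
  list(ped = ped, flips = data.frame(id = flips, from = from, to = to,
                                     stringsAsFactors = FALSE))
}

.randBases <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  clash <- alt == ref
  while (any(clash)) {
    alt[clash] <- sample(c("A", "C", "G", "T"), sum(clash), replace = TRUE)
    clash <- alt == ref
  }
  list(ref = ref, alt = alt)
}

.emptyAnnRow <- function(n, chrom, pos, ref, alt, gene = NA_character_,
                         funcClass = "noncoding") {
  out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    gene = gene, funcClass = funcClass,
                    stringsAsFactors = FALSE)
  for (p in .POPULATIONS) out[[p]] <- NA_real_
  out$inDbsnp <- FALSE; out$inEsp <- FALSE; out$espFreq <- NA_real_
  for (p in .PREDICTORS) out[[p]] <- NA_character_
  out$key <- variantKey(chrom, pos, ref, alt)
  out
}

.drawPredictors <- function(n, pDamaging, pMissing = 0.05) {
  m <- matrix(NA_character_, n, length(.PREDICTORS),
              dimnames = list(NULL, .PREDICTORS))
  for (j in seq_along(.PREDICTORS)) {
    u <- runif(n)
    m[, j] <- ifelse(u < pMissing, NA_character_,
                     ifelse(runif(n) < pDamaging, "D", "T"))
  }
  m
}

.randomGeneTable <- function(cfg) {
  lens <- cfg$chromLengths
  nG <- cfg$nBackgroundGenes
  counts <- setNames(pmax(1, round(nG * lens / sum(lens))), names(lens))
  rows <- list()
  gi <- 0
  for (ch in names(lens)) {
    for (k in seq_len(counts[[ch]])) {
      gi <- gi + 1
      glen <- round(runif(1, 5e3, 8e4))
      start <- floor(runif(1, 0, lens[[ch]] - glen))
      rows[[gi]] <- .mkGene(ch, start, start + glen,
                            sprintf("GENE%04d", gi))
    }
  }
  do.call(rbind, rows)
}

.mkGene <- function(chrom, start, end, symbol, strand = "+") {
  len <- end - start
  nEx <- sample(2:5, 1)
  cuts <- sort(runif(2 * nEx, 0.02, 0.98)) * len
  es <- round(start + cuts[seq(1, 2 * nEx, 2)])
  ee <- round(start + cuts[seq(2, 2 * nEx, 2)])
  ok <- es < ee
  es <- es[ok]; ee <- ee[ok]
  if (!length(es)) { es <- start; ee <- end }
  data.frame(chrom = chrom, start = start, end = end, symbol = symbol,
             strand = strand, exon_starts = paste(es, collapse = ","),
             exon_ends = paste(ee, collapse = ","),
             cds_start = es[1], cds_end = ee[length(ee)],
             stringsAsFactors = FALSE)
}

.scenarioTargets <- c(dominant = "Fam02", recessive_hom = "Fam05",
                      compound_het = "Fam05", x_linked = "Fam05",
                      de_novo = "Fam14", ssr_ld_block = "Fam01",
                      denovo_cnv = "Fam14")

#' Simulate a synthetic family cohort
#'
#' Generates decoy variants gene-dropped independently per family from
#' per-population founder frequencies, plants exactly the configured causal
#' scenario in one target family (the causal allele is absent from every
#' other family), annotates everything, applies label noise to the emitted
#' pedigrees only, and records the ground truth in a manifest. Fully
#' deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @return a \linkS4class{SimulatedCohort}.
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "scenarioConfig"))
  cfg <- config
  lens <- cfg$chromLengths
  set.seed(cfg$seed %% .seedMod)

  ## --- gene table, decoy sites and population frequencies -------------
  genes <- .randomGeneTable(cfg)
  nD <- cfg$nDecoys
  chrom <- sample(names(lens), nD, replace = TRUE, prob = lens / sum(lens))
  pos <- floor(runif(nD) * (lens[chrom] - 1)) + 1
  keep <- !duplicated(paste(chrom, pos))
  chrom <- chrom[keep]; pos <- unname(pos[keep]); nD <- sum(keep)
  ba <- .randBases(nD)
  common <- runif(nD) < cfg$commonFraction
  m <- numeric(nD)
  m[common] <- runif(sum(common), 0.02, 0.25)
  m[!common] <- pmax(1e-4, pmin(rexp(sum(!common), rate = 1 / 0.004), 0.02))
  popFreq <- matrix(pmin(0.6, m * exp(rnorm(nD * 5, 0, 0.3))), nD, 5,
                    dimnames = list(NULL, .POPULATIONS))
  founderFreq <- popFreq[, "EAS"]

  ## --- pedigrees and gene dropping -------------------------------------
  tmpl <- .templates()
  plan <- .familyPlan()
  peds <- list()
  carrierSets <- list()
  doseCols <- list()
  xIdx <- which(chrom == cfg$xChrom)
  for (i in seq_len(nrow(plan))) {
    inst <- .instantiate(plan$template[i], plan$family[i], tmpl)
    ped <- inst$ped
    peds[[plan$family[i]]] <- ped
    carrierSets[[plan$family[i]]] <- inst$carriers
    set.seed((cfg$seed * 131 + i * 7919) %% .seedMod)
    dose <- .dropFamily(ped@members, founderFreq, xIdx)
    doseCols[[i]] <- dose[, sequencedIds(ped), drop = FALSE]
  }
  geno <- do.call(cbind, doseCols)
  variants <- data.frame(chrom = chrom, pos = pos, ref = ba$ref,
                         alt = ba$alt, stringsAsFactors = FALSE)

  ## --- decoy annotation -------------------------------------------------
  set.seed((cfg$seed * 131 + 104729) %% .seedMod)
  fc <- sample(c("noncoding", "synonymous", "missense",
                 "nonframeshift_indel", "frameshift_indel", "splicing",
                 "nonsense"), nD, replace = TRUE,
               prob = c(0.55, 0.17, 0.25, 0.015, 0.006, 0.005, 0.004))
  ann <- data.frame(chrom = chrom, pos = pos, ref = ba$ref, alt = ba$alt,
                    gene = NA_character_, funcClass = fc,
                    stringsAsFactors = FALSE)
  recorded <- popFreq
  recorded[recorded < 5e-4] <- NA
  for (p in .POPULATIONS) ann[[p]] <- recorded[, p]
  ann$inDbsnp <- runif(nD) < ifelse(m >= 0.001, 0.95, 0.2)
  ann$inEsp <- common & runif(nD) < 0.9
  ann$espFreq <- ifelse(ann$inEsp, pmin(0.6, m * exp(rnorm(nD, 0, 0.3))),
                        NA_real_)
  pm <- matrix(NA_character_, nD, length(.PREDICTORS),
               dimnames = list(NULL, .PREDICTORS))
  mis <- fc == "missense"
  pm[mis, ] <- .drawPredictors(sum(mis), cfg$predBenign)
  for (p in .PREDICTORS) ann[[p]] <- pm[, p]
  ## gene assignment: containing background gene, if any
  ann$gene <- .geneAt(genes, chrom, pos)
  ann$key <- variantKey(chrom, pos, ba$ref, ba$alt)
  variants$key <- ann$key

  ## --- plant the causal scenario ----------------------------------------
  set.seed((cfg$seed * 131 + 224737) %% .seedMod)
  target <- .scenarioTargets[[cfg$scenario]]
  tped <- peds[[target]]
  plant <- .plantScenario(cfg, tped, genes, colnames(geno),
                          carrierSets[[target]])
  genes <- plant$genes
  if (nrow(plant$variants)) {
    clash <- variants$key %in% plant$variants$key |
      paste(variants$chrom, variants$pos) %in%
        paste(plant$variants$chrom, plant$variants$pos)
    if (any(clash)) {      # a decoy landed on a planted site: decoy yields
      variants <- variants[!clash, , drop = FALSE]
      geno <- geno[!clash, , drop = FALSE]
      ann <- ann[!clash, , drop = FALSE]
    }
    variants <- rbind(variants, plant$variants[, names(variants)])
    geno <- rbind(geno, plant$geno[, colnames(geno), drop = FALSE])
    ann <- rbind(ann, plant$ann[, names(ann)])
  }

  ## --- genotype noise ----------------------------------------------------
  set.seed((cfg$seed * 131 + 350377) %% .seedMod)
  nv <- nrow(geno); ns <- ncol(geno)
  if (cfg$dropoutRate > 0) {
    drop <- geno >= 1 & matrix(runif(nv * ns) < cfg$dropoutRate, nv, ns)
    geno[drop] <- geno[drop] - 1
  }
  if (cfg$missingRate > 0)
    geno[matrix(runif(nv * ns) < cfg$missingRate, nv, ns)] <- NA

  ## --- label noise (emitted PED only) ------------------------------------
  set.seed((cfg$seed * 131 + 499979) %% .seedMod)
  truthLabels <- affectionLabels(tped)
  flips <- data.frame(id = character(), from = character(), to = character())
  if (cfg$nLabelFlips > 0) {
    mm <- tped@members
    pool <- mm$id[mm$sequenced & mm$labelConfidence == "soft" &
                    mm$affection == (if (cfg$flipDirection == "case_to_control")
                      "affected" else "unaffected")]
    if (cfg$scenario != "denovo_cnv" && length(plant$keepAffected))
      pool <- setdiff(pool, plant$keepAffected)
    if (length(pool) < cfg$nLabelFlips)
      stop("not enough flippable members for the requested label noise")
    sel <- sort(sample(pool, cfg$nLabelFlips))
    noisy <- injectLabelNoise(tped, sel)
    peds[[target]] <- noisy$ped
    flips <- noisy$flips
  }

  ## --- order variants, assemble ------------------------------------------
  ord <- order(match(variants$chrom, names(lens)), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  ann <- ann[ord, , drop = FALSE]
  rownames(variants) <- rownames(ann) <- NULL
  cohort <- GenotypeCohort(variants, geno)
  cohort <- setSampleFamilies(cohort, peds)

  truth <- list(scenario = cfg$scenario, targetFamily = target,
                mode = plant$mode, causalKeys = plant$causalKeys,
                causalGene = plant$causalGene, flips = flips,
                truthLabels = as.list(truthLabels),
                hiddenLocus = plant$hiddenLocus, block = plant$block,
                cnv = plant$cnv, seed = cfg$seed)
  new("SimulatedCohort", cohort = cohort, pedigrees = peds,
      annotations = ann, cnv = plant$cnvTable, genes = genes,
      truth = truth, config = unclass(cfg))
}

.geneAt <- function(genes, chrom, pos) {
  out <- rep(NA_character_, length(chrom))
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1, genes$end))
  vr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(vr, gr, select = "first")
  ok <- !is.na(hits)
  out[ok] <- genes$symbol[hits[ok]]
  out
}

## Build the planted causal event for one scenario. Returns variant rows,
## their dosage rows over all cohort samples, annotation rows, possibly
## extended gene table, CNV tables and truth fields.
.plantScenario <- function(cfg, tped, genes, allSamples,
                           carrierSet = character()) {
  lens <- cfg$chromLengths
  zeroGeno <- function(n) matrix(0, n, length(allSamples),
                                 dimnames = list(NULL, allSamples))
  fid <- familyId(tped)
  mid <- function(x) paste(fid, x, sep = "_")
  out <- list(variants = data.frame(), geno = zeroGeno(0),
              ann = data.frame(), genes = genes, mode = NA_character_,
              causalKeys = character(), causalGene = NA_character_,
              hiddenLocus = NULL, block = NULL, cnv = NULL,
              cnvTable = data.frame(chrom = character(), start = numeric(),
                                    end = numeric(), state = character(),
                                    sample = character(),
                                    stringsAsFactors = FALSE),
              keepAffected = character())

  mkCausal <- function(chrom, pos, dose, funcClass, gene,
                       damaging = TRUE) {
    ba <- .randBases(1)
    ann <- .emptyAnnRow(1, chrom, pos, ba$ref, ba$alt, gene, funcClass)
    if (funcClass == "missense") {
      pc <- .drawPredictors(1, if (damaging) cfg$predDamaging else cfg$predBenign)
      for (p in .PREDICTORS) ann[[p]] <- pc[, p]
    }
    g <- zeroGeno(1)
    g[1, names(dose)] <- dose
    list(variants = data.frame(chrom = chrom, pos = pos, ref = ba$ref,
                               alt = ba$alt, key = ann$key,
                               stringsAsFactors = FALSE),
         geno = g, ann = ann)
  }
  randAutoPos <- function() {
    auto <- setdiff(names(lens), cfg$xChrom)
    ch <- sample(auto, 1, prob = lens[auto] / sum(lens[auto]))
    list(chrom = ch, pos = floor(runif(1, 1e6, lens[[ch]] - 1e6)))
  }
  addCausalGene <- function(chrom, pos, symbol) {
    g <- .mkGene(chrom, max(0, pos - 6000), min(lens[[chrom]], pos + 6000),
                 symbol)
    out$genes <<- rbind(out$genes, g)
    symbol
  }

  scen <- cfg$scenario
  if (scen == "dominant") {
    loc <- randAutoPos()
    carriers <- intersect(carrierSet, sequencedIds(tped))
    gene <- addCausalGene(loc$chrom, loc$pos, "CAUSAL1")
    cv <- mkCausal(loc$chrom, loc$pos, setNames(rep(1, length(carriers)),
                                                carriers), "missense", gene)
    out$variants <- cv$variants; out$geno <- cv$geno; out$ann <- cv$ann
    out$mode <- "dominant"; out$causalKeys <- cv$variants$key
    out$causalGene <- gene
    out$keepAffected <- character()     # all affected are carriers
  } else if (scen == "recessive_hom") {
    loc <- randAutoPos()
    gene <- addCausalGene(loc$chrom, loc$pos, "CAUSAL1")
    dose <- setNames(c(1, 1, 2, 2), mid(c("fat", "mot", "s1", "s2")))
    cv <- mkCausal(loc$chrom, loc$pos, dose, "missense", gene)
    out$variants <- cv$variants; out$geno <- cv$geno; out$ann <- cv$ann
    out$mode <- "recessive_hom"; out$causalKeys <- cv$variants$key
    out$causalGene <- gene
  } else if (scen == "compound_het") {
    loc <- randAutoPos()
    pos2 <- loc$pos + 2000
    g <- .mkGene(loc$chrom, max(0, loc$pos - 6000), pos2 + 6000, "CAUSAL1")
    out$genes <- rbind(out$genes, g)
    d1 <- setNames(c(1, 0, 1, 1), mid(c("fat", "mot", "s1", "s2")))
    d2 <- setNames(c(0, 1, 1, 1), mid(c("fat", "mot", "s1", "s2")))
    cv1 <- mkCausal(loc$chrom, loc$pos, d1, "frameshift_indel", "CAUSAL1")
    cv2 <- mkCausal(loc$chrom, pos2, d2, "nonsense", "CAUSAL1")
    out$variants <- rbind(cv1$variants, cv2$variants)
    out$geno <- rbind(cv1$geno, cv2$geno)
    out$ann <- rbind(cv1$ann, cv2$ann)
    out$mode <- "compound_het"
    out$causalKeys <- out$variants$key
    out$causalGene <- "CAUSAL1"
  } else if (scen == "x_linked") {
    pos <- floor(runif(1, 1e6, lens[[cfg$xChrom]] - 1e6))
    gene <- addCausalGene(cfg$xChrom, pos, "CAUSAL1")
    dose <- setNames(c(0, 1, 2, 2), mid(c("fat", "mot", "s1", "s2")))
    cv <- mkCausal(cfg$xChrom, pos, dose, "missense", gene)
    out$variants <- cv$variants; out$geno <- cv$geno; out$ann <- cv$ann
    out$mode <- "x_linked"; out$causalKeys <- cv$variants$key
    out$causalGene <- gene
  } else if (scen == "de_novo") {
    loc <- randAutoPos()
    gene <- addCausalGene(loc$chrom, loc$pos, "CAUSAL1")
    dose <- setNames(c(0, 0, 1), mid(c("fat", "mot", "c1")))
    cv <- mkCausal(loc$chrom, loc$pos, dose, "missense", gene)
    out$variants <- cv$variants; out$geno <- cv$geno; out$ann <- cv$ann
    out$mode <- "de_novo"; out$causalKeys <- cv$variants$key
    out$causalGene <- gene
  } else if (scen == "ssr_ld_block") {
    ch <- "chr14"
    half <- cfg$blockSpan / 2
    center <- floor(runif(1, half + 5e6, lens[[ch]] - half - 5e6))
    locus <- floor(center + runif(1, -cfg$locusJitter, cfg$locusJitter))
    nb <- cfg$blockVariants
    nCore <- floor(nb / 2)
    p1 <- round(rnorm(nCore, locus, 1e6))
    p2 <- round(runif(nb - nCore, center - half, center + half))
    bpos <- sort(unique(pmin(pmax(c(p1, p2), center - half), center + half)))
    carriers <- intersect(carrierSet, sequencedIds(tped))
    ba <- .randBases(length(bpos))
    ann <- .emptyAnnRow(length(bpos), ch, bpos, ba$ref, ba$alt,
                        NA_character_, "noncoding")
    g <- zeroGeno(length(bpos))
    g[, carriers] <- 1
    out$variants <- data.frame(chrom = ch, pos = bpos, ref = ba$ref,
                               alt = ba$alt, key = ann$key,
                               stringsAsFactors = FALSE)
    out$geno <- g
    out$ann <- ann
    out$mode <- "dominant"
    out$causalKeys <- character()       # hidden locus has no variant record
    out$hiddenLocus <- list(chrom = ch, pos = locus)
    out$block <- list(chrom = ch, start = center - half,
                      end = center + half, center = center)
    ## the hidden repeat locus sits inside a real gene; tile neighbors so
    ## the distance ranking has competition
    out$causalGene <- "TARGETG"
    tg <- .mkGene(ch, max(0, locus - 25000), locus + 25000, "TARGETG")
    nbr <- lapply(c(-4e6, -2.5e6, -1.2e6, 1.5e6, 3e6), function(off)
      .mkGene(ch, locus + off, locus + off + 40000,
              sprintf("NBR%+d", round(off / 1e6))))
    out$genes <- rbind(out$genes, tg, do.call(rbind, nbr))
  } else if (scen == "denovo_cnv") {
    child <- mid("c1"); fat <- mid("fat"); mot <- mid("mot")
    planted <- data.frame(chrom = "chr3", start = 0, end = 10349999,
                          state = "loss", sample = child,
                          stringsAsFactors = FALSE)
    decoy <- function(sampleId) {
      n <- cfg$cnvDecoysPerParent
      ch <- sample(setdiff(names(lens), "chr3"), n, replace = TRUE)
      len <- round(runif(n, 1e5, 2e6))
      st <- floor(runif(n, 0, lens[ch] - len))
      data.frame(chrom = ch, start = st, end = st + len,
                 state = sample(c("loss", "gain"), n, replace = TRUE),
                 sample = sampleId, stringsAsFactors = FALSE)
    }
    fSegs <- decoy(fat); mSegs <- decoy(mot)
    inherit <- function(segs) {
      jit <- round((segs$end - segs$start) * runif(nrow(segs), -0.02, 0.02))
      data.frame(chrom = segs$chrom, start = pmax(0, segs$start + jit),
                 end = segs$end + jit, state = segs$state, sample = child,
                 stringsAsFactors = FALSE)
    }
    cTab <- rbind(planted, inherit(fSegs), inherit(mSegs), fSegs, mSegs)
    out$cnvTable <- cTab[order(cTab$chrom, cTab$start), ]
    rownames(out$cnvTable) <- NULL
    out$cnv <- planted
    out$mode <- "de_novo"
    ## three genes inside the lost segment, mirroring a contiguous-gene loss
    gl <- lapply(1:3, function(k)
      .mkGene("chr3", 2e6 * k, 2e6 * k + 60000, sprintf("LOSS%d", k)))
    out$genes <- rbind(out$genes, do.call(rbind, gl))
  }
  out$genes <- out$genes[order(out$genes$chrom, out$genes$start), ]
  rownames(out$genes) <- NULL
  out
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the formats the readers consume: \code{cohort.vcf},
#' \code{cohort.ped}, \code{annotations.tsv}, \code{cnv.tsv},
#' \code{genes.tsv} and \code{truth.json}.
#'
#' @param sim a \linkS4class{SimulatedCohort}.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             ped = file.path(dir, "cohort.ped"),
             ann = file.path(dir, "annotations.tsv"),
             cnv = file.path(dir, "cnv.tsv"),
             genes = file.path(dir, "genes.tsv"),
             truth = file.path(dir, "truth.json"))
  writeVcfCohort(sim@cohort, paths["vcf"])
  writePed(sim@pedigrees, paths["ped"])
  writeAnnotations(sim@annotations, paths["ann"])
  writeCnvTable(sim@cnv, paths["cnv"])
  writeGeneTable(sim@genes, paths["genes"])
  jsonlite::write_json(sim@truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}

#' Check Mendelian consistency of cohort genotypes
#'
#' For every member with both parents among the cohort samples, flags
#' variants whose observed dosages are impossible under Mendelian
#' transmission (a carried allele absent from both parents, a homozygous
#' child with a non-carrier parent, and so on). Missing calls are skipped.
#' X-chromosome males are checked against the mother only.
#'
#' @param cohort a \linkS4class{GenotypeCohort}.
#' @param pedigrees list of \linkS4class{Pedigree}.
#' @param xChrom chromosome treated as X.
#' @return data.frame of violations: \code{key}, \code{family}, \code{child}.
#' @export
checkMendelian <- function(cohort, pedigrees, xChrom = "chrX") {
  G <- cohort@geno
  v <- cohort@variants
  isX <- v$chrom == xChrom
  out <- list()
  for (ped in pedigrees) {
    m <- ped@members
    for (i in seq_len(nrow(m))) {
      child <- m$id[i]
      fa <- m$fatherId[i]; mo <- m$motherId[i]
      if (is.na(fa) || is.na(mo)) next
      if (!all(c(child, fa, mo) %in% colnames(G))) next
      gc <- G[, child]; gf <- G[, fa]; gm <- G[, mo]
      maleX <- isX & m$sex[i] == "male"
      bad <-
        (!maleX & !is.na(gc) & (
          (gc == 2 & ((!is.na(gf) & gf == 0) | (!is.na(gm) & gm == 0))) |
            (gc == 0 & ((!is.na(gf) & gf == 2) | (!is.na(gm) & gm == 2))) |
            (gc >= 1 & !is.na(gf) & gf == 0 & !is.na(gm) & gm == 0) |
            (gc <= 1 & !is.na(gf) & gf == 2 & !is.na(gm) & gm == 2))) |
        (maleX & !is.na(gc) & !is.na(gm) & (
          (gc >= 1 & gm == 0) | (gc == 0 & gm == 2)))
      if (any(bad))
        out[[length(out) + 1]] <- data.frame(
          key = v$key[bad], family = familyId(ped), child = child,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(key = character(), family = character(),
                      child = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
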