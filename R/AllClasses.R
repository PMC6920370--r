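#' @import methods
#' @importFrom stats median rbinom rexp rnorm runif setNames p.adjust binom.test
#' @importFrom utils combn read.delim write.table
NULL

.SEXES <- c("male", "female", "unknown")
.AFFECTIONS <- c("affected", "unaffected", "unknown")
.CONFIDENCES <- c("firm", "soft")
.MODELS <- c("dominant", "recessive_hom", "compound_het", "x_linked", "de_novo")
.PREDICTORS <- c("SIFT", "PolyPhen", "LRT", "MutationTaster",
                 "MutationAssessor", "FATHMM", "MetaSVM", "MetaLR")
.POPULATIONS <- c("AFR", "AMR", "EAS", "EUR", "SAS")
.FUNC_CLASSES <- c("frameshift_indel", "nonframeshift_indel", "missense",
                   "nonsense", "splicing", "synonymous", "noncoding")

#' Pedigree of one family
#'
#' Holds the members of a single family: identifiers, parental links, sex,
#' affection status, a firm/soft confidence flag on the affection label, and
#' whether the individual was sequenced. Affection status drives the
#' segregation filters; the confidence flag controls which labels the
#' misclassification-tolerant search may flip.
#'
#' @slot familyId single family identifier.
#' @slot members data.frame with columns \code{id}, \code{fatherId},
#'   \code{motherId} (\code{NA} for founders), \code{sex}
#'   (male/female/unknown), \code{affection} (affected/unaffected/unknown),
#'   \code{labelConfidence} (firm/soft) and \code{sequenced} (logical).
#' @export
setClass("Pedigree",
         representation(familyId = "character", members = "data.frame"))

.pedigreeValidity <- function(object) {
  m <- object@members
  msgs <- character()
  need <- c("id", "fatherId", "motherId", "sex", "affection",
            "labelConfidence", "sequenced")
  if (!all(need %in% names(m)))
    return(paste("members lacks columns:",
                 paste(setdiff(need, names(m)), collapse = ", ")))
  if (anyDuplicated(m$id))
    msgs <- c(msgs, sprintf("duplicate individual id(s): %s",
                            paste(unique(m$id[duplicated(m$id)]), collapse = ", ")))
  for (col in c("fatherId", "motherId")) {
    ref <- m[[col]][!is.na(m[[col]])]
    bad <- setdiff(ref, m$id)
    if (length(bad))
      msgs <- c(msgs, sprintf("%s references undefined member(s): %s",
                              col, paste(bad, collapse = ", ")))
  }
  if (!all(m$sex %in% .SEXES)) msgs <- c(msgs, "invalid sex value")
  if (!all(m$affection %in% .AFFECTIONS)) msgs <- c(msgs, "invalid affection value")
  if (!all(m$labelConfidence %in% .CONFIDENCES))
    msgs <- c(msgs, "invalid labelConfidence value")
  fa <- m$sex[match(m$fatherId[!is.na(m$fatherId)], m$id)]
  if (any(fa == "female", na.rm = TRUE))
    msgs <- c(msgs, "a referenced father has sex female")
  mo <- m$sex[match(m$motherId[!is.na(m$motherId)], m$id)]
  if (any(mo == "male", na.rm = TRUE))
    msgs <- c(msgs, "a referenced mother has sex male")
  if (!any(m$affection == "affected"))
    msgs <- c(msgs, "pedigree has no affected member")
  if (length(msgs) == 0 && .hasPedigreeCycle(m))
    msgs <- c(msgs, "parent relation is cyclic")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
}

.hasPedigreeCycle <- function(m) {
  # depth-bounded ancestor walk; a cycle means some walk never terminates
  idx <- seq_len(nrow(m))
  names(idx) <- m$id
  for (start in idx) {
    seen <- logical(nrow(m))
    frontier <- start
    while (length(frontier)) {
      if (any(seen[frontier])) return(TRUE)
      seen[frontier] <- TRUE
      par <- c(m$fatherId[frontier], m$motherId[frontier])
      frontier <- unname(idx[par[!is.na(par)]])
    }
  }
  FALSE
}

setValidity("Pedigree", .pedigreeValidity)

#' Construct a Pedigree
#'
#' Unknown sex of a referenced father or mother is inferred from the role and
#' fixed before validation.
#'
#' @param familyId family identifier.
#' @param members data.frame as documented in \linkS4class{Pedigree}.
#' @return A \linkS4class{Pedigree}.
#' @export
Pedigree <- function(familyId, members) {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  rownames(members) <- NULL
  isFather <- members$id %in% members$fatherId[!is.na(members$fatherId)]
  isMother <- members$id %in% members$motherId[!is.na(members$motherId)]
  members$sex[isFather & members$sex == "unknown"] <- "male"
  members$sex[isMother & members$sex == "unknown"] <- "female"
  new("Pedigree", familyId = as.character(familyId), members = members)
}

#' Multi-sample genotype container
#'
#' Biallelic variant sites with one alt-allele dosage per sample: 0, 1, 2 or
#' \code{NA} (missing call). Hemizygous male X genotypes may be coded 0/1 or
#' 1/1 upstream; both appear here as dosage >= 1.
#'
#' @slot variants data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}, \code{key}.
#' @slot geno numeric matrix, variants x samples, dosage of the alt allele.
#' @slot gq optional numeric matrix of genotype qualities (same shape) or NULL.
#' @slot sampleFamily named character vector mapping sample id to family id
#'   (may be empty until pedigrees are attached).
#' @export
setClass("GenotypeCohort",
         representation(variants = "data.frame", geno = "matrix",
                        gq = "ANY", sampleFamily = "character"))

setValidity("GenotypeCohort", function(object) {
  v <- object@variants
  msgs <- character()
  need <- c("chrom", "pos", "ref", "alt", "key")
  if (!all(need %in% names(v))) return("variants lacks required columns")
  if (nrow(v) != nrow(object@geno)) return("variants/geno row mismatch")
  if (is.null(colnames(object@geno))) return("geno must have sample colnames")
  if (any(v$pos < 1)) msgs <- c(msgs, "pos must be >= 1")
  if (any(v$ref == v$alt)) msgs <- c(msgs, "ref equals alt")
  ok <- object@geno %in% c(0, 1, 2) | is.na(object@geno)
  if (!all(ok)) msgs <- c(msgs, "dosages must be 0, 1, 2 or NA")
  if (length(object@sampleFamily) &&
      !all(names(object@sampleFamily) %in% colnames(object@geno)))
    msgs <- c(msgs, "sampleFamily names not all cohort samples")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a GenotypeCohort
#'
#' @param variants data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} (a \code{key} column is derived if absent).
#' @param geno dosage matrix with sample column names.
#' @param gq optional genotype-quality matrix.
#' @param sampleFamily named character vector sample -> family.
#' @return A \linkS4class{GenotypeCohort}.
#' @export
GenotypeCohort <- function(variants, geno, gq = NULL,
                           sampleFamily = character()) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (is.null(variants$key))
    variants$key <- variantKey(variants$chrom, variants$pos,
                               variants$ref, variants$alt)
  rownames(variants) <- NULL
  geno <- as.matrix(geno)
  storage.mode(geno) <- "double"
  new("GenotypeCohort", variants = variants, geno = geno, gq = gq,
      sampleFamily = sampleFamily)
}

#' Canonical variant key
#'
#' @param chrom,pos,ref,alt variant coordinates and alleles.
#' @return character \code{chrom:pos:ref:alt}.
#' @export
variantKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Enriched chromosome region from the variant-density scan
#'
#' @slot chrom chromosome name.
#' @slot peakStart,peakEnd 0-based half-open span of the maximal-count window.
#' @slot runStart,runEnd span of the enriched run (contiguous windows with
#'   count >= half the peak count, containing the peak window).
#' @slot peakCenter median position of variants in the peak window, rounded
#'   to 1 kb.
#' @slot intervalStart,intervalEnd candidate interval peakCenter +/- halfWidth,
#'   clipped to the chromosome.
#' @slot pValue,qValue chromosome-level binomial enrichment p and BH q value.
#' @slot nVariants number of variants on the chromosome.
#' @export
setClass("EnrichedRegion",
         representation(chrom = "character", peakStart = "numeric",
                        peakEnd = "numeric", runStart = "numeric",
                        runEnd = "numeric", peakCenter = "numeric",
                        intervalStart = "numeric", intervalEnd = "numeric",
                        pValue = "numeric", qValue = "numeric",
                        nVariants = "numeric"))

#' Synthetic cohort bundle
#'
#' Everything one simulated study emits: genotypes, pedigrees, annotation,
#' CNV segments, gene intervals, and the truth manifest recording what was
#' planted.
#'
#' @slot cohort \linkS4class{GenotypeCohort}.
#' @slot pedigrees named list of \linkS4class{Pedigree}.
#' @slot annotations annotation data.frame (see \code{\link{readAnnotations}}).
#' @slot cnv CNV segment data.frame.
#' @slot genes gene interval data.frame.
#' @slot truth list: planted causal keys, mode, injected label flips, hidden
#'   locus, planted CNV.
#' @slot config the \code{\link{scenarioConfig}} used.
#' @export
setClass("SimulatedCohort",
         representation(cohort = "GenotypeCohort", pedigrees = "list",
                        annotations = "data.frame", cnv = "data.frame",
                        genes = "data.frame", truth = "list", config = "list"))

## ---- generics & accessors ----

#' @describeIn Pedigree family identifier
#' @param object a Pedigree
#' @export
setGeneric("familyId", function(object) standardGeneric("familyId"))
#' @export
setMethod("familyId", "Pedigree", function(object) object@familyId)

#' Member table of a pedigree
#' @param object a \linkS4class{Pedigree}
#' @return data.frame of members
#' @export
setGeneric("pedMembers", function(object) standardGeneric("pedMembers"))
#' @export
setMethod("pedMembers", "Pedigree", function(object) object@members)

#' Affection labels of a pedigree as a named vector
#' @param object a \linkS4class{Pedigree}
#' @return named character vector id -> affection
#' @export
setGeneric("affectionLabels", function(object) standardGeneric("affectionLabels"))
#' @export
setMethod("affectionLabels", "Pedigree", function(object)
  setNames(object@members$affection, object@members$id))

#' Ids of sequenced members
#' @param object a \linkS4class{Pedigree}
#' @export
setGeneric("sequencedIds", function(object) standardGeneric("sequencedIds"))
#' @export
setMethod("sequencedIds", "Pedigree", function(object)
  object@members$id[object@members$sequenced])

setMethod("show", "Pedigree", function(object) {
  m <- object@members
  cat(sprintf("Pedigree %s: %d members (%d sequenced; %d affected, %d unaffected, %d unknown)\n",
              object@familyId, nrow(m), sum(m$sequenced),
              sum(m$affection == "affected"), sum(m$affection == "unaffected"),
              sum(m$affection == "unknown")))
})

#' Variant table of a cohort
#' @param object a \linkS4class{GenotypeCohort}
#' @export
setGeneric("variantTable", function(object) standardGeneric("variantTable"))
#' @export
setMethod("variantTable", "GenotypeCohort", function(object) object@variants)

#' Variant keys
#' @param object a \linkS4class{GenotypeCohort}
#' @export
setGeneric("variantKeys", function(object) standardGeneric("variantKeys"))
#' @export
setMethod("variantKeys", "GenotypeCohort", function(object) object@variants$key)

#' Alt-allele dosage matrix
#' @param object a \linkS4class{GenotypeCohort}
#' @export
setGeneric("genoMatrix", function(object) standardGeneric("genoMatrix"))
#' @export
setMethod("genoMatrix", "GenotypeCohort", function(object) object@geno)

#' Sample identifiers
#' @param object a \linkS4class{GenotypeCohort}
#' @export
setGeneric("cohortSamples", function(object) standardGeneric("cohortSamples"))
#' @export
setMethod("cohortSamples", "GenotypeCohort", function(object)
  colnames(object@geno))

#' Sample-to-family map
#' @param object a \linkS4class{GenotypeCohort}
#' @export
setGeneric("sampleFamilies", function(object) standardGeneric("sampleFamilies"))
#' @export
setMethod("sampleFamilies", "GenotypeCohort", function(object)
  object@sampleFamily)

#' Attach a sample-to-family map from pedigrees
#' @param object a \linkS4class{GenotypeCohort}
#' @param pedigrees list of \linkS4class{Pedigree}
#' @return the cohort with \code{sampleFamilies} filled for samples found in
#'   the pedigrees
#' @export
setGeneric("setSampleFamilies",
           function(object, pedigrees) standardGeneric("setSampleFamilies"))
#' @export
setMethod("setSampleFamilies", "GenotypeCohort", function(object, pedigrees) {
  map <- do.call(c, unname(lapply(pedigrees, function(p)
    setNames(rep(familyId(p), nrow(p@members)), p@members$id))))
  samp <- colnames(object@geno)
  object@sampleFamily <- map[intersect(samp, names(map))]
  object
})

setMethod("show", "GenotypeCohort", function(object) {
  cat(sprintf("GenotypeCohort: %d variants x %d samples (%d families mapped)\n",
              nrow(object@variants), ncol(object@geno),
              length(unique(object@sampleFamily))))
})

setMethod("show", "EnrichedRegion", function(object) {
  cat(sprintf("EnrichedRegion %s: peak window [%s, %s), center %s, candidate interval [%s, %s), n=%d, q=%.3g\n",
              object@chrom, format(object@peakStart, big.mark = ","),
              format(object@peakEnd, big.mark = ","),
              format(object@peakCenter, big.mark = ","),
              format(object@intervalStart, big.mark = ","),
              format(object@intervalEnd, big.mark = ","),
              object@nVariants, object@qValue))
})

#' Candidate interval of an enriched region
#' @param object an \linkS4class{EnrichedRegion}
#' @return numeric length-2 vector (start, end), 0-based half-open
#' @export
setGeneric("candidateInterval",
           function(object) standardGeneric("candidateInterval"))
#' @export
setMethod("candidateInterval", "EnrichedRegion", function(object)
  c(object@intervalStart, object@intervalEnd))

#' Peak center of an enriched region
#' @param object an \linkS4class{EnrichedRegion}
#' @export
setGeneric("peakCenter", function(object) standardGeneric("peakCenter"))
#' @export
setMethod("peakCenter", "EnrichedRegion", function(object) object@peakCenter)

#' Truth manifest of a simulated cohort
#' @param object a \linkS4class{SimulatedCohort}
#' @export
setGeneric("truthManifest", function(object) standardGeneric("truthManifest"))
#' @export
setMethod("truthManifest", "SimulatedCohort", function(object) object@truth)

#' Genotype cohort of a simulation
#' @param object a \linkS4class{SimulatedCohort}
#' @export
setGeneric("cohortOf", function(object) standardGeneric("cohortOf"))
#' @export
setMethod("cohortOf", "SimulatedCohort", function(object) object@cohort)

#' Pedigrees of a simulation
#' @param object a \linkS4class{SimulatedCohort}
#' @export
setGeneric("pedigreesOf", function(object) standardGeneric("pedigreesOf"))
#' @export
setMethod("pedigreesOf", "SimulatedCohort", function(object) object@pedigrees)

#' Annotation table of a simulation
#' @param object a \linkS4class{SimulatedCohort}
#' @export
setGeneric("annotationsOf", function(object) standardGeneric("annotationsOf"))
#' @export
setMethod("annotationsOf", "SimulatedCohort", function(object)
  object@annotations)

setMethod("show", "SimulatedCohort", function(object) {
  cat(sprintf("SimulatedCohort: scenario '%s', %d families, %d samples, %d variants (seed %s)\n",
              object@truth$scenario, length(object@pedigrees),
              ncol(object@cohort@geno), nrow(object@cohort@variants),
              format(object@config$seed)))
})
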