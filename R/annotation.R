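## Functional classification against a minimal gene model, population
## frequency / database filters, and the predictor consensus vote.

#' Default 1000 Genomes multi-population frequency-removal rule
#'
#' A variant is removed when, for any clause, at least \code{minPops}
#' populations have frequency >= \code{threshold}. The default clauses are
#' (1, 0.05), (2, 0.03), (3, 0.025), (4, 0.02) over the five 1000G
#' super-populations.
#'
#' @return data.frame with columns \code{minPops}, \code{threshold}.
#' @export
defaultFreqRule <- function() {
  data.frame(minPops = 1:4, threshold = c(0.05, 0.03, 0.025, 0.02))
}

.checkRule <- function(rule) {
  stopifnot(all(c("minPops", "threshold") %in% names(rule)))
  rule <- rule[order(rule$minPops), , drop = FALSE]
  if (nrow(rule) > 1 && any(diff(rule$threshold) >= 0))
    stop("frequency rule thresholds must strictly decrease as minPops increases")
  rule
}

#' Parse a "k:t,k:t" frequency-rule string
#' @param spec e.g. "1:0.05,2:0.03,3:0.025,4:0.02".
#' @return rule data.frame as in \code{\link{defaultFreqRule}}.
#' @export
parseFreqRule <- function(spec) {
  parts <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  .checkRule(data.frame(minPops = as.integer(vapply(parts, `[`, "", 1L)),
                        threshold = as.numeric(vapply(parts, `[`, "", 2L))))
}

#' Population-frequency filter
#'
#' @param popFreq numeric vector of per-population frequencies; populations
#'   in which the variant was not observed are simply absent (or NA). An
#'   empty map (novel variant) is always kept.
#' @param rule rule data.frame (see \code{\link{defaultFreqRule}}).
#' @return \code{"remove"} or \code{"keep"}.
#' @export
frequencyFilter <- function(popFreq, rule = defaultFreqRule()) {
  .checkRule(rule)
  f <- popFreq[!is.na(popFreq)]
  rm <- any(vapply(seq_len(nrow(rule)), function(i)
    sum(f >= rule$threshold[i]) >= rule$minPops[i], TRUE))
  if (rm) "remove" else "keep"
}

## vectorized: freqMat is n x pop, NA = unobserved
.freqRemove <- function(freqMat, rule = defaultFreqRule()) {
  rm <- rep(FALSE, nrow(freqMat))
  for (i in seq_len(nrow(rule)))
    rm <- rm | rowSums(freqMat >= rule$threshold[i], na.rm = TRUE) >=
      rule$minPops[i]
  rm
}

#' Database filter (dbSNP / 1000G / ESP)
#'
#' Default policy: remove iff the 1000G frequency rule removes, or the
#' variant is in NHLBI-ESP with a recorded frequency reaching the rule's
#' single-population threshold. Bare dbSNP membership without frequency data
#' does not remove (known pathogenic alleles are in dbSNP). The strict
#' policy additionally removes any dbSNP member.
#'
#' @param popFreq numeric per-population frequencies (NA/absent = unobserved).
#' @param inDbsnp logical dbSNP membership flag.
#' @param inEsp logical ESP membership flag.
#' @param espFreq ESP frequency or NA.
#' @param rule frequency rule (see \code{\link{defaultFreqRule}}).
#' @param policy \code{"default"} or \code{"strict"}.
#' @return \code{"remove"} or \code{"keep"}.
#' @export
databaseFilter <- function(popFreq, inDbsnp = FALSE, inEsp = FALSE,
                           espFreq = NA_real_, rule = defaultFreqRule(),
                           policy = c("default", "strict")) {
  policy <- match.arg(policy)
  t1 <- min(rule$threshold[rule$minPops == 1], 0.05)
  rm <- frequencyFilter(popFreq, rule) == "remove" ||
    (isTRUE(inEsp) && !is.na(espFreq) && espFreq >= t1) ||
    (policy == "strict" && isTRUE(inDbsnp))
  if (rm) "remove" else "keep"
}

## vectorized over an annotation data.frame
.dbRemove <- function(ann, rule = defaultFreqRule(),
                      policy = c("default", "strict")) {
  policy <- match.arg(policy)
  t1 <- min(rule$threshold[rule$minPops == 1], 0.05)
  freqMat <- as.matrix(ann[, .POPULATIONS, drop = FALSE])
  rm <- .freqRemove(freqMat, rule) |
    (ann$inEsp & !is.na(ann$espFreq) & ann$espFreq >= t1)
  if (policy == "strict") rm <- rm | ann$inDbsnp
  rm
}

#' Predictor consensus vote
#'
#' Truncating classes (nonsense, frameshift indel, canonical splice) are
#' deleterious unconditionally: the predictors score protein-altering SNVs
#' and do not apply. Missense is deleterious iff damaging calls strictly
#' outnumber tolerated calls among non-missing predictors (ties and
#' all-missing are not deleterious). A non-frameshift indel is deleterious
#' iff any predictor calls it damaging. Synonymous and noncoding variants
#' are never deleterious.
#'
#' @param funcClass one of the functional classes (see
#'   \code{\link{classifyFunctional}}).
#' @param predCalls character vector of predictor calls, "D"/"T"/NA.
#' @return \code{"deleterious"} or \code{"not_deleterious"}.
#' @export
deleteriousVote <- function(funcClass, predCalls = character()) {
  stopifnot(funcClass %in% .FUNC_CLASSES)
  del <- switch(funcClass,
    nonsense = , frameshift_indel = , splicing = TRUE,
    missense = sum(predCalls == "D", na.rm = TRUE) >
      sum(predCalls == "T", na.rm = TRUE),
    nonframeshift_indel = any(predCalls == "D", na.rm = TRUE),
    FALSE)
  if (del) "deleterious" else "not_deleterious"
}

## vectorized over an annotation data.frame
.voteDeleterious <- function(ann) {
  pm <- as.matrix(ann[, .PREDICTORS, drop = FALSE])
  nD <- rowSums(pm == "D", na.rm = TRUE)
  nT <- rowSums(pm == "T", na.rm = TRUE)
  fc <- ann$funcClass
  fc %in% c("nonsense", "frameshift_indel", "splicing") |
    (fc == "missense" & nD > nT) |
    (fc == "nonframeshift_indel" & nD > 0)
}

#' Classify a variant's functional effect against a minimal gene model
#'
#' Rules, applied per overlapped gene: a variant touching the two intronic
#' bases flanking any coding exon boundary (the canonical splice
#' dinucleotide) is \code{splicing}; an indel overlapping coding sequence is
#' a \code{frameshift_indel} when the allele-length difference is not a
#' multiple of 3, else \code{nonframeshift_indel}; a coding SNV is
#' \code{synonymous}, \code{nonsense} (new stop) or \code{missense} by codon
#' translation; anything else (non-coding gene regions, intergenic) is
#' \code{noncoding}. A variant overlapping several genes yields one record
#' per gene.
#'
#' @param chrom,pos,ref,alt the variant (VCF convention, \code{pos} 1-based).
#' @param genes gene-interval data.frame (see \code{\link{readGeneTable}}).
#' @param refSeqs named character vector (or DNAStringSet) of reference
#'   sequence per chromosome; position 1 of the sequence is genomic
#'   position 1.
#' @return data.frame with columns \code{gene}, \code{funcClass}; one row
#'   per overlapped gene, or a single \code{NA}-gene noncoding row when the
#'   variant lies outside all genes.
#' @export
classifyFunctional <- function(chrom, pos, ref, alt, genes, refSeqs) {
  p0 <- pos - 1                       # 0-based start
  span <- c(p0, p0 + nchar(ref))      # half-open genomic footprint
  hit <- genes[genes$chrom == chrom & genes$start < span[2] &
                 genes$end > span[1], , drop = FALSE]
  if (nrow(hit) == 0)
    return(data.frame(gene = NA_character_, funcClass = "noncoding",
                      stringsAsFactors = FALSE))
  if (nrow(hit) > 1)
    message(sprintf("variant %s overlaps %d genes; emitting one record per gene",
                    variantKey(chrom, pos, ref, alt), nrow(hit)))
  res <- lapply(seq_len(nrow(hit)), function(i)
    .classifyOne(hit[i, ], span, ref, alt, refSeqs[[chrom]]))
  data.frame(gene = hit$symbol, funcClass = unlist(res),
             stringsAsFactors = FALSE)
}

.classifyOne <- function(g, span, ref, alt, chromSeq) {
  es <- .splitNum(g$exon_starts); ee <- .splitNum(g$exon_ends)
  ces <- pmax(es, g$cds_start); cee <- pmin(ee, g$cds_end)
  keep <- ces < cee
  ces <- ces[keep]; cee <- cee[keep]
  if (!length(ces)) return("noncoding")

  # canonical +/-2 splice dinucleotides: flanks of coding exon boundaries
  # that are intronic (i.e. not covered by any exon of the gene)
  flanks <- rbind(cbind(ces - 2, ces), cbind(cee, cee + 2))
  inExon <- function(a, b) any(es < b & ee > a)
  intronic <- !apply(flanks, 1, function(fl) inExon(fl[1], fl[2]))
  flanks <- flanks[intronic, , drop = FALSE]
  if (nrow(flanks) &&
      any(flanks[, 1] < span[2] & flanks[, 2] > span[1]))
    return("splicing")

  overlapsCds <- any(ces < span[2] & cee > span[1])
  if (nchar(ref) != 1 || nchar(alt) != 1) {
    if (!overlapsCds) return("noncoding")
    d <- abs(nchar(ref) - nchar(alt))
    return(if (d %% 3 != 0) "frameshift_indel" else "nonframeshift_indel")
  }
  if (!overlapsCds) return("noncoding")

  cdsPos <- unlist(mapply(function(a, b) seq(a, b - 1), ces, cee,
                          SIMPLIFY = FALSE))            # 0-based, ascending
  idx <- match(span[1], cdsPos)
  if (is.na(idx)) return("noncoding")
  chromSeq <- as.character(chromSeq)
  baseAt <- function(j) substr(chromSeq, cdsPos[j] + 1, cdsPos[j] + 1)
  n <- length(cdsPos)
  if (g$strand == "-") idx <- n - idx + 1
  codonIdx <- (idx - 1) %/% 3
  off <- (idx - 1) %% 3
  jj <- codonIdx * 3 + 1:3                              # CDS coordinates
  gj <- if (g$strand == "+") jj else n - jj + 1         # genomic exon index
  bases <- vapply(gj, baseAt, "")                       # in coding order
  if (g$strand == "-") bases <- .compBases(bases)
  refCodon <- paste(bases, collapse = "")
  altBase <- if (g$strand == "+") alt else .compBases(alt)
  altCodon <- refCodon
  substr(altCodon, off + 1, off + 1) <- altBase
  if (nchar(refCodon) < 3) return("noncoding")          # truncated terminal codon
  aaRef <- .translateCodon(refCodon)
  aaAlt <- .translateCodon(altCodon)
  if (aaRef == aaAlt) "synonymous"
  else if (aaAlt == "*") "nonsense"
  else "missense"
}

.compBases <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  unname(comp[x])
}

.translateCodon <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

#' Annotate missing variants as novel
#'
#' Aligns an annotation table to a set of variant keys; keys without a row
#' get an empty record (novel variant: no gene, noncoding unless told
#' otherwise, empty frequencies, no database flags, all predictors missing).
#'
#' @param ann annotation data.frame from \code{\link{readAnnotations}}.
#' @param keys character vector of variant keys to cover.
#' @return annotation data.frame with one row per key, in key order.
#' @export
alignAnnotations <- function(ann, keys) {
  if (is.null(ann) || nrow(ann) == 0) {
    ann <- data.frame(chrom = "", pos = 0, ref = "", alt = "",
                      gene = NA_character_, funcClass = "noncoding",
                      stringsAsFactors = FALSE)
    for (p in .POPULATIONS) ann[[p]] <- NA_real_
    ann$inDbsnp <- FALSE; ann$inEsp <- FALSE; ann$espFreq <- NA_real_
    for (p in .PREDICTORS) ann[[p]] <- NA_character_
    ann$key <- ""
  }
  idx <- match(keys, ann$key)
  out <- ann[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
  novel <- is.na(idx)
  if (any(novel)) {
    out$gene[novel] <- NA_character_
    out$funcClass[novel] <- "noncoding"
    for (p in .POPULATIONS) out[[p]][novel] <- NA_real_
    out$inDbsnp[novel] <- FALSE
    out$inEsp[novel] <- FALSE
    out$espFreq[novel] <- NA_real_
    for (p in .PREDICTORS) out[[p]][novel] <- NA_character_
  }
  out$key <- keys
  rownames(out) <- NULL
  out
}
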