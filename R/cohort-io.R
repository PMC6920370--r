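## Readers and writers for the formats the pipeline touches:
## multi-sample VCF (GT, optional GQ), annotation TSV, BED-like CNV segment
## and gene-interval tables.

#' Read a multi-sample VCF into a GenotypeCohort
#'
#' Supports the VCF 4.2 subset the pipeline needs: CHROM/POS/REF/ALT plus
#' per-sample GT (and optional GQ). Multiallelic records are split into one
#' biallelic record per alt allele with allele indices remapped; at a given
#' split record, a sample's other alt alleles are treated as missing, so a
#' 1/2 call is dosage 1 (het) in both derived records and a 2/2 call is
#' missing in the record for alt 1.
#'
#' @param path VCF path (plain text or gzip).
#' @return A \linkS4class{GenotypeCohort} with records in file order (each
#'   multiallelic site contributing alts in ALT order).
#' @export
readVcfCohort <- function(path) {
  hdr <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) break
    if (startsWith(ln, "#CHROM")) { hdr <- ln; break }
    if (!startsWith(ln, "##")) break
  }
  if (!length(hdr) || !startsWith(hdr, "#CHROM"))
    stop("VCF format error: missing #CHROM header line")
  close(con); on.exit()
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(v@gt) || ncol(v@gt) < 2)
    stop("VCF format error: no sample genotype columns")
  fmt <- v@gt[, "FORMAT"]
  if (!all(vapply(strsplit(fmt, ":"), function(x) "GT" %in% x, TRUE)))
    stop("VCF format error: GT absent from FORMAT")
  samples <- setdiff(colnames(v@gt), "FORMAT")
  gtIdx <- vapply(strsplit(fmt, ":"), function(x) match("GT", x), 1L)
  gqIdx <- vapply(strsplit(fmt, ":"), function(x) match("GQ", x), 1L)
  hasGQ <- any(!is.na(gqIdx))

  nrec <- nrow(v@fix)
  outV <- vector("list", nrec)
  outG <- vector("list", nrec)
  outQ <- if (hasGQ) vector("list", nrec) else NULL
  for (i in seq_len(nrec)) {
    alts <- strsplit(v@fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    cells <- v@gt[i, samples]
    parts <- strsplit(ifelse(is.na(cells), ".", cells), ":", fixed = TRUE)
    gt <- vapply(parts, `[`, "", gtIdx[i])
    alleles <- strsplit(gt, "[/|]")
    gq <- if (hasGQ && !is.na(gqIdx[i]))
      suppressWarnings(as.numeric(vapply(parts, function(x)
        if (length(x) >= gqIdx[i]) x[gqIdx[i]] else NA_character_, "")))
    else rep(NA_real_, length(samples))
    nAlt <- length(alts)
    doseM <- matrix(NA_real_, nAlt, length(samples))
    for (s in seq_along(samples)) {
      a <- alleles[[s]]
      for (j in seq_len(nAlt)) {
        known <- sum(a == as.character(j))
        nNA <- sum(a == "." | !(a %in% c("0", as.character(j))))
        doseM[j, s] <- if (nNA == 0) known else if (known > 0) known else NA_real_
      }
    }
    outV[[i]] <- data.frame(chrom = unname(v@fix[i, "CHROM"]),
                            pos = as.numeric(v@fix[i, "POS"]),
                            ref = unname(v@fix[i, "REF"]), alt = alts,
                            stringsAsFactors = FALSE)
    outG[[i]] <- doseM
    if (hasGQ) outQ[[i]] <- matrix(rep(gq, each = nAlt), nAlt,
                                   length(samples))
  }
  variants <- do.call(rbind, outV)
  geno <- do.call(rbind, outG)
  colnames(geno) <- samples
  gqm <- NULL
  if (hasGQ) { gqm <- do.call(rbind, outQ); colnames(gqm) <- samples }
  GenotypeCohort(variants, geno, gq = gqm)
}

#' Write a GenotypeCohort as VCF
#'
#' Emits the biallelic VCF 4.2 subset read by \code{\link{readVcfCohort}}:
#' dosage 0 -> 0/0, 1 -> 0/1, 2 -> 1/1, NA -> ./., with GQ when present.
#'
#' @param cohort a \linkS4class{GenotypeCohort}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVcfCohort <- function(cohort, path) {
  v <- cohort@variants
  g <- cohort@geno
  gtStr <- matrix(c("0/0", "0/1", "1/1")[g + 1], nrow(g), ncol(g))
  gtStr[is.na(g)] <- "./."
  fmt <- "GT"
  if (!is.null(cohort@gq)) {
    q <- cohort@gq
    qs <- ifelse(is.na(q), ".", format(q, trim = TRUE, scientific = FALSE))
    gtStr <- matrix(paste(gtStr, qs, sep = ":"), nrow(g), ncol(g))
    fmt <- "GT:GQ"
  }
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(g)), collapse = "\t"))
  body <- paste(v$chrom, format(v$pos, trim = TRUE, scientific = FALSE),
                ".", v$ref, v$alt, ".", ".", ".", fmt, sep = "\t")
  if (nrow(g))
    body <- paste(body, apply(gtStr, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

.annCols <- function() c("chrom", "pos", "ref", "alt", "gene", "func_class",
                         .POPULATIONS, "dbsnp", "esp", "esp_freq", .PREDICTORS)

#' Read a per-variant annotation table
#'
#' Tab-separated with header columns \code{chrom, pos, ref, alt, gene,
#' func_class, AFR, AMR, EAS, EUR, SAS, dbsnp, esp, esp_freq} and the eight
#' predictor columns (SIFT, PolyPhen, LRT, MutationTaster, MutationAssessor,
#' FATHMM, MetaSVM, MetaLR). Empty frequency cells mean "not observed in that
#' population". Predictor cells: \code{D} = damaging, \code{T} = tolerated,
#' \code{.} or empty = missing. On duplicate (chrom,pos,ref,alt) keys the
#' last row wins with a warning.
#'
#' @param path TSV path.
#' @return data.frame keyed by \code{key}; variants absent from the table
#'   are simply absent (treat as novel: empty frequencies, no flags).
#' @export
readAnnotations <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE)
  need <- .annCols()
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  numify <- function(col, nm) {
    raw <- d[[col]]
    blank <- is.na(raw) | raw == "" | raw == "."
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!blank & is.na(val))
    if (length(bad))
      stop(sprintf("annotation row error: malformed numeric '%s' in column %s at line %d",
                   raw[bad[1]], nm, bad[1] + 1L))
    val[blank] <- NA_real_
    val
  }
  out <- data.frame(chrom = d$chrom, pos = numify("pos", "pos"),
                    ref = d$ref, alt = d$alt,
                    gene = ifelse(d$gene %in% c("", "."), NA_character_, d$gene),
                    funcClass = d$func_class, stringsAsFactors = FALSE)
  if (!all(out$funcClass %in% .FUNC_CLASSES))
    stop("annotation row error: unknown func_class value")
  for (p in .POPULATIONS) out[[p]] <- numify(p, p)
  out$inDbsnp <- d$dbsnp %in% c("1", "TRUE", "true", "yes")
  out$inEsp <- d$esp %in% c("1", "TRUE", "true", "yes")
  out$espFreq <- numify("esp_freq", "esp_freq")
  for (p in .PREDICTORS) {
    raw <- d[[p]]
    if (!all(raw %in% c("D", "T", ".", "")))
      stop(sprintf("annotation row error: predictor cell must be D, T or . (column %s)", p))
    out[[p]] <- ifelse(raw %in% c(".", ""), NA_character_, raw)
  }
  out$key <- variantKey(out$chrom, out$pos, out$ref, out$alt)
  dup <- duplicated(out$key, fromLast = TRUE)
  if (any(dup)) {
    warning(sprintf("annotation table: %d duplicate key(s); last row wins",
                    sum(dup)))
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write an annotation table
#' @param ann data.frame in the layout returned by \code{\link{readAnnotations}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(ann, path) {
  fmtNum <- function(x) ifelse(is.na(x), "", sprintf("%.12g", x))
  d <- data.frame(chrom = ann$chrom, pos = fmtNum(ann$pos), ref = ann$ref,
                  alt = ann$alt, gene = ifelse(is.na(ann$gene), ".", ann$gene),
                  func_class = ann$funcClass, stringsAsFactors = FALSE,
                  check.names = FALSE)
  for (p in .POPULATIONS) d[[p]] <- fmtNum(ann[[p]])
  d$dbsnp <- as.integer(ann$inDbsnp)
  d$esp <- as.integer(ann$inEsp)
  d$esp_freq <- fmtNum(ann$espFreq)
  for (p in .PREDICTORS) d[[p]] <- ifelse(is.na(ann[[p]]), ".", ann[[p]])
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CNV segment table
#'
#' BED-like TSV with header \code{chrom, start, end, state, sample};
#' 0-based half-open coordinates; state is \code{loss} or \code{gain}.
#' Output is sorted by (chrom, start).
#'
#' @param path TSV path.
#' @return data.frame of segments.
#' @export
readCnvTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), state = character(),
                      sample = character(), stringsAsFactors = FALSE))
  need <- c("chrom", "start", "end", "state", "sample")
  if (!all(need %in% names(d)))
    stop("CNV table lacks column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d$start <- as.numeric(d$start); d$end <- as.numeric(d$end)
  bad <- which(!(d$start >= 0 & d$start < d$end))
  if (length(bad))
    stop(sprintf("CNV table row error at line %d: need 0 <= start < end",
                 bad[1] + 1L))
  if (!all(d$state %in% c("loss", "gain")))
    stop("CNV table row error: state must be 'loss' or 'gain'")
  d <- d[order(d$chrom, d$start, d$end), need]
  rownames(d) <- NULL
  d
}

#' Read a gene-interval table
#'
#' BED-like TSV with header \code{chrom, start, end, symbol, strand,
#' exon_starts, exon_ends, cds_start, cds_end}; 0-based half-open; exon
#' columns are comma-separated lists, sorted, non-overlapping and within
#' [start, end). Output is sorted by (chrom, start).
#'
#' @param path TSV path.
#' @return data.frame of gene intervals.
#' @export
readGeneTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  cols <- c("chrom", "start", "end", "symbol", "strand",
            "exon_starts", "exon_ends", "cds_start", "cds_end")
  if (nrow(d) == 0)
    return(stats::setNames(data.frame(matrix(ncol = 9, nrow = 0)), cols))
  if (!all(cols %in% names(d)))
    stop("gene table lacks column(s): ",
         paste(setdiff(cols, names(d)), collapse = ", "))
  for (col in c("start", "end", "cds_start", "cds_end"))
    d[[col]] <- as.numeric(d[[col]])
  bad <- which(!(d$start >= 0 & d$start < d$end))
  if (length(bad))
    stop(sprintf("gene table row error at line %d: need 0 <= start < end",
                 bad[1] + 1L))
  if (!all(d$strand %in% c("+", "-")))
    stop("gene table row error: strand must be '+' or '-'")
  for (i in seq_len(nrow(d))) {
    es <- .splitNum(d$exon_starts[i]); ee <- .splitNum(d$exon_ends[i])
    if (length(es) != length(ee) || any(es >= ee) ||
        is.unsorted(es, strictly = TRUE) ||
        (length(es) > 1 && any(es[-1] < ee[-length(ee)])) ||
        any(es < d$start[i]) || any(ee > d$end[i]))
      stop(sprintf("gene table row error at line %d: invalid exon structure",
                   i + 1L))
  }
  d <- d[order(d$chrom, d$start, d$end), cols]
  rownames(d) <- NULL
  d
}

.splitNum <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])

#' Write CNV segment / gene interval tables
#' @param d data.frame in the corresponding reader's layout.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCnvTable <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCnvTable
#' @export
writeGeneTable <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Preflight consistency check on cohort inputs
#'
#' Verifies that chromosome naming is internally consistent across the
#' genotype, CNV and gene tables (names are taken verbatim; no "chr"
#' stripping) and that every pedigree sample claimed sequenced is present in
#' the cohort.
#'
#' @param cohort a \linkS4class{GenotypeCohort}.
#' @param pedigrees list of \linkS4class{Pedigree} (optional).
#' @param cnv CNV segment data.frame (optional).
#' @param genes gene interval data.frame (optional).
#' @return character vector of problems (length 0 when clean).
#' @export
preflightCohort <- function(cohort, pedigrees = NULL, cnv = NULL,
                            genes = NULL) {
  probs <- character()
  chroms <- unique(cohort@variants$chrom)
  pref <- startsWith(chroms, "chr")
  if (length(chroms) && !all(pref) && any(pref))
    probs <- c(probs, "mixed chromosome naming in variant table")
  for (nm in c("cnv", "genes")) {
    d <- get(nm)
    if (!is.null(d) && nrow(d)) {
      p2 <- startsWith(unique(d$chrom), "chr")
      if (any(p2) != all(p2) || (length(chroms) && any(pref) != any(p2)))
        probs <- c(probs, sprintf("chromosome naming in %s table differs from variants", nm))
    }
  }
  if (!is.null(pedigrees)) {
    seqIds <- unlist(lapply(pedigrees, sequencedIds))
    miss <- setdiff(seqIds, cohortSamples(cohort))
    if (length(miss))
      probs <- c(probs, sprintf("sequenced pedigree member(s) absent from cohort: %s",
                                paste(miss, collapse = ", ")))
  }
  probs
}
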