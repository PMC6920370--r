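## Chromosome-level enrichment of co-segregating filtered variants and
## sliding-window localization of the peak region. Co-segregation is
## enforced upstream (the scan consumes variants that already passed a
## segregation filter); the scan itself is genotype-agnostic.

#' Human-genome chromosome lengths (GRCh37-style)
#'
#' Named vector of chromosome lengths for chr1-chr22 and chrX, used as the
#' default genome model by the scan and the synthetic generator.
#'
#' @return named numeric vector of lengths in bp.
#' @export
defaultChromLengths <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516,
    chr12 = 133851895, chr13 = 115169878, chr14 = 107349540,
    chr15 = 102531392, chr16 = 90354753, chr17 = 81195210,
    chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566, chrX = 155270560)
}

#' Chromosome-level variant-density enrichment test
#'
#' For each chromosome, a one-sided binomial test of the observed variant
#' count against the expectation proportional to chromosome length,
#' Benjamini-Hochberg adjusted across chromosomes.
#'
#' @param variants data.frame with \code{chrom} and \code{pos}.
#' @param chromLengths named vector of chromosome lengths
#'   (default \code{\link{defaultChromLengths}}).
#' @param alpha flag chromosomes with BH q-value below this (default 0.05).
#' @return data.frame per chromosome: \code{chrom}, \code{n},
#'   \code{expected}, \code{pValue}, \code{qValue}, \code{flagged}; sorted
#'   by q-value. Zero input variants give an empty result with a warning.
#' @export
chromEnrichment <- function(variants, chromLengths = defaultChromLengths(),
                            alpha = 0.05) {
  if (nrow(variants) == 0) {
    warning("no variants supplied; empty enrichment result")
    return(data.frame(chrom = character(), n = integer(),
                      expected = numeric(), pValue = numeric(),
                      qValue = numeric(), flagged = logical()))
  }
  nTot <- nrow(variants)
  counts <- table(factor(variants$chrom, levels = names(chromLengths)))
  p <- chromLengths / sum(chromLengths)
  pv <- vapply(seq_along(chromLengths), function(i)
    binom.test(counts[i], nTot, p[i], alternative = "greater")$p.value, 1)
  qv <- p.adjust(pv, method = "BH")
  out <- data.frame(chrom = names(chromLengths), n = as.integer(counts),
                    expected = nTot * as.numeric(p), pValue = pv, qValue = qv,
                    flagged = qv < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$qValue, -out$n), ]
  rownames(out) <- NULL
  out
}

#' Sliding-window scan of one chromosome
#'
#' Counts variants in sliding windows, takes the maximal-count window as the
#' peak (ties broken toward the smallest start), defines the enriched run as
#' the maximal contiguous stretch of windows containing the peak with count
#' at least half the peak count, sets the peak center to the median position
#' of variants inside the peak window (rounded to 1 kb), and returns the
#' candidate interval peak center +/- \code{halfWidth}, clipped to the
#' chromosome.
#'
#' @param positions numeric vector of 1-based variant positions on the
#'   chromosome (at least one).
#' @param chromLength chromosome length in bp.
#' @param chrom chromosome name (for the report).
#' @param windowSize window size in bp (default 1 Mb).
#' @param step window step in bp (default 0.5 Mb).
#' @param halfWidth candidate-interval half width (default 1 Mb).
#' @return list with \code{profile} (data.frame \code{start}, \code{end},
#'   \code{count} per window) and \code{region}
#'   (\linkS4class{EnrichedRegion}; p/q values are NA here and filled by
#'   \code{\link{densityScan}}).
#' @export
windowScan <- function(positions, chromLength, chrom = "chr?",
                       windowSize = 1e6, step = 5e5, halfWidth = 1e6) {
  if (windowSize <= 0) stop("windowSize must be positive")
  if (step <= 0) stop("step must be positive")
  if (!length(positions)) stop("at least one variant position required")
  starts <- seq(0, max(0, chromLength - windowSize), by = step)
  if (max(starts) + windowSize < chromLength)
    starts <- c(starts, chromLength - windowSize)
  sp <- sort(positions)
  # window [s, s+w) in 0-based terms holds 1-based positions s+1 .. s+w
  counts <- findInterval(starts + windowSize + 0.5, sp) -
    findInterval(starts + 0.5, sp)
  peak <- which.max(counts)                       # first max = smallest start
  half <- counts[peak] / 2
  lo <- peak; hi <- peak
  while (lo > 1 && counts[lo - 1] >= half) lo <- lo - 1
  while (hi < length(counts) && counts[hi + 1] >= half) hi <- hi + 1
  inPeak <- positions > starts[peak] & positions <= starts[peak] + windowSize
  center <- round(median(positions[inPeak]) / 1000) * 1000
  iv <- c(max(0, center - halfWidth), min(chromLength, center + halfWidth))
  region <- new("EnrichedRegion", chrom = chrom,
                peakStart = starts[peak], peakEnd = starts[peak] + windowSize,
                runStart = starts[lo], runEnd = starts[hi] + windowSize,
                peakCenter = center, intervalStart = iv[1],
                intervalEnd = iv[2], pValue = NA_real_, qValue = NA_real_,
                nVariants = length(positions))
  list(profile = data.frame(start = starts, end = starts + windowSize,
                            count = as.integer(counts)),
       region = region)
}

#' Full variant-density scan
#'
#' Runs \code{\link{chromEnrichment}} and then \code{\link{windowScan}} on
#' every flagged chromosome.
#'
#' @inheritParams chromEnrichment
#' @inheritParams windowScan
#' @return list with \code{chromStats} (the enrichment table),
#'   \code{regions} (list of \linkS4class{EnrichedRegion}, one per flagged
#'   chromosome, with p/q filled in) and \code{profiles} (per-window counts
#'   per flagged chromosome).
#' @export
densityScan <- function(variants, chromLengths = defaultChromLengths(),
                        alpha = 0.05, windowSize = 1e6, step = 5e5,
                        halfWidth = 1e6) {
  stats <- chromEnrichment(variants, chromLengths, alpha)
  flagged <- stats$chrom[stats$flagged]
  regions <- list()
  profiles <- list()
  for (ch in flagged) {
    sc <- windowScan(variants$pos[variants$chrom == ch], chromLengths[[ch]],
                     chrom = ch, windowSize = windowSize, step = step,
                     halfWidth = halfWidth)
    sc$region@pValue <- stats$pValue[stats$chrom == ch]
    sc$region@qValue <- stats$qValue[stats$chrom == ch]
    regions[[ch]] <- sc$region
    profiles[[ch]] <- sc$profile
  }
  list(chromStats = stats, regions = regions, profiles = profiles)
}

#' Genes overlapping an enriched region's candidate interval
#'
#' @param region an \linkS4class{EnrichedRegion}.
#' @param genes gene-interval data.frame (see \code{\link{readGeneTable}}).
#' @return the overlapping rows of \code{genes} with an added
#'   \code{distance} column (gene midpoint to peak center), sorted by
#'   distance.
#' @export
candidateGenes <- function(region, genes) {
  iv <- candidateInterval(region)
  hit <- genes[genes$chrom == region@chrom & genes$start < iv[2] &
                 genes$end > iv[1], , drop = FALSE]
  if (nrow(hit) == 0) { hit$distance <- numeric(); return(hit) }
  hit$distance <- abs((hit$start + hit$end) / 2 - peakCenter(region))
  hit <- hit[order(hit$distance, hit$start), ]
  rownames(hit) <- NULL
  hit
}
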