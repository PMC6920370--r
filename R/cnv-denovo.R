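## De novo CNV segment detection by reciprocal overlap against parental
## segment calls, plus overlapped-gene annotation. Segments arrive
## pre-called (read-depth CNV calling is upstream of this package).

.segOverlap <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Classify an affected child's CNV segments as de novo or inherited
#'
#' A child segment is inherited from a parent when some same-state parental
#' segment reaches the reciprocal-overlap threshold
#' (overlap / child length >= t AND overlap / parent length >= t);
#' otherwise it is de novo. Only loss-vs-loss and gain-vs-gain overlaps
#' count.
#'
#' @param child,mother,father CNV segment data.frames (columns \code{chrom},
#'   \code{start}, \code{end}, \code{state}; 0-based half-open).
#' @param minReciprocalOverlap threshold t in (0, 1] (default 0.5).
#' @param genes optional gene table; when given, overlapped gene symbols are
#'   attached per segment.
#' @return data.frame: child segments with \code{inheritedFrom}
#'   (none/mother/father/both), \code{bestParentalOverlap} (best reciprocal
#'   fraction over both parents) and, when \code{genes} is given,
#'   \code{genes} (comma-joined symbols).
#' @export
denovoSegments <- function(child, mother, father,
                           minReciprocalOverlap = 0.5, genes = NULL) {
  t <- minReciprocalOverlap
  if (length(t) != 1 || is.na(t) || t <= 0 || t > 1)
    stop("minReciprocalOverlap must be in (0, 1]")
  bestRecip <- function(seg, parent) {
    if (is.null(parent) || nrow(parent) == 0) return(0)
    cand <- parent[parent$chrom == seg$chrom & parent$state == seg$state, ,
                   drop = FALSE]
    if (nrow(cand) == 0) return(0)
    ov <- .segOverlap(seg$start, seg$end, cand$start, cand$end)
    recip <- pmin(ov / (seg$end - seg$start), ov / (cand$end - cand$start))
    max(recip)
  }
  n <- nrow(child)
  out <- child
  out$inheritedFrom <- character(n)
  out$bestParentalOverlap <- numeric(n)
  if (!is.null(genes)) out$genes <- character(n)
  for (i in seq_len(n)) {
    bm <- bestRecip(child[i, ], mother)
    bf <- bestRecip(child[i, ], father)
    out$inheritedFrom[i] <- if (bm >= t && bf >= t) "both"
      else if (bm >= t) "mother" else if (bf >= t) "father" else "none"
    out$bestParentalOverlap[i] <- max(bm, bf)
    if (!is.null(genes))
      out$genes[i] <- paste(segmentGenes(child[i, ], genes), collapse = ",")
  }
  rownames(out) <- NULL
  out
}

#' Gene symbols overlapped by a segment
#'
#' Any gene with at least 1 bp overlap counts; coordinates are 0-based
#' half-open, so a gene exactly abutting the segment end is excluded.
#'
#' @param seg one-row CNV segment data.frame (or list with \code{chrom},
#'   \code{start}, \code{end}).
#' @param genes gene-interval data.frame.
#' @return character vector of symbols, coordinate-sorted.
#' @export
segmentGenes <- function(seg, genes) {
  hit <- genes[genes$chrom == seg$chrom & genes$start < seg$end &
                 genes$end > seg$start, , drop = FALSE]
  hit$symbol[order(hit$start)]
}
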