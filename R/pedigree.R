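## PED parsing and affection-label relabeling enumeration.

#' Parse a PED pedigree file
#'
#' PLINK-dialect 6-column whitespace-delimited PED: family, individual,
#' father, mother, sex (1 = male, 2 = female, 0 = unknown), phenotype
#' (2 = affected, 1 = unaffected, 0 = unknown). A parent code of "0" means
#' founder. An optional 7th column "firm"/"soft" sets the label-confidence
#' flag; everyone defaults to soft (flippable by the relabeling search).
#' Parsed individuals are marked sequenced; use \code{\link{markSequenced}}
#' to restrict to the samples actually present in a VCF.
#'
#' @param path path to a PED file, or NULL when \code{text} is given.
#' @param text character vector of PED lines (alternative to \code{path}).
#' @return named list of \linkS4class{Pedigree}, one per family id.
#' @export
parsePed <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("PED input is empty")
  tok <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(tok)
  if (any(nf < 6))
    stop(sprintf("PED parse error: line %d has %d fields (6 required)",
                 which(nf < 6)[1], nf[nf < 6][1]))
  rec <- data.frame(
    family = vapply(tok, `[`, "", 1L), id = vapply(tok, `[`, "", 2L),
    father = vapply(tok, `[`, "", 3L), mother = vapply(tok, `[`, "", 4L),
    sexCode = vapply(tok, `[`, "", 5L), affCode = vapply(tok, `[`, "", 6L),
    conf = vapply(tok, function(x) if (length(x) >= 7) x[7] else "soft", ""),
    stringsAsFactors = FALSE)
  dup <- duplicated(paste(rec$family, rec$id))
  if (any(dup))
    stop(sprintf("PED parse error: duplicate (family, id) pair '%s %s' at line %d",
                 rec$family[dup][1], rec$id[dup][1], which(dup)[1]))
  if (!all(rec$conf %in% .CONFIDENCES))
    stop("PED parse error: 7th column must be 'firm' or 'soft'")
  sexMap <- c("1" = "male", "2" = "female", "0" = "unknown")
  affMap <- c("2" = "affected", "1" = "unaffected", "0" = "unknown")
  if (!all(rec$sexCode %in% names(sexMap)))
    stop("PED parse error: sex code must be 1, 2 or 0")
  if (!all(rec$affCode %in% names(affMap)))
    stop("PED parse error: phenotype code must be 2, 1 or 0")
  peds <- lapply(split(rec, factor(rec$family, unique(rec$family))),
                 function(r) {
    Pedigree(r$family[1], data.frame(
      id = r$id,
      fatherId = ifelse(r$father == "0", NA_character_, r$father),
      motherId = ifelse(r$mother == "0", NA_character_, r$mother),
      sex = unname(sexMap[r$sexCode]),
      affection = unname(affMap[r$affCode]),
      labelConfidence = r$conf,
      sequenced = TRUE,
      stringsAsFactors = FALSE))
  })
  peds
}

#' Write pedigrees to a PED file
#'
#' Emits the 7-column dialect read by \code{\link{parsePed}} (the 7th column
#' is the firm/soft confidence flag), so that write -> parse round-trips.
#'
#' @param pedigrees a \linkS4class{Pedigree} or list of them.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePed <- function(pedigrees, path) {
  if (is(pedigrees, "Pedigree")) pedigrees <- list(pedigrees)
  sexMap <- c(male = "1", female = "2", unknown = "0")
  affMap <- c(affected = "2", unaffected = "1", unknown = "0")
  lines <- unlist(lapply(pedigrees, function(p) {
    m <- p@members
    paste(p@familyId, m$id,
          ifelse(is.na(m$fatherId), "0", m$fatherId),
          ifelse(is.na(m$motherId), "0", m$motherId),
          sexMap[m$sex], affMap[m$affection], m$labelConfidence,
          sep = "\t")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Mark which pedigree members were sequenced
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param sampleIds ids present in the genotype data. Members not listed are
#'   retained for structure (parent inference) but never constrain
#'   genotype-based filters.
#' @return the updated Pedigree.
#' @export
markSequenced <- function(ped, sampleIds) {
  ped@members$sequenced <- ped@members$id %in% sampleIds
  validObject(ped)
  ped
}

.flippableIds <- function(ped) {
  m <- ped@members
  sort(m$id[m$sequenced & m$labelConfidence == "soft" &
              m$affection != "unknown"])
}

.flipAffection <- function(labels, ids) {
  labels[ids] <- ifelse(labels[ids] == "affected", "unaffected", "affected")
  labels
}

#' Enumerate affection-label reassignments
#'
#' Yields every assignment obtained by flipping affected <-> unaffected on
#' 0..\code{maxFlips} soft-labeled sequenced members, ordered by ascending
#' flip count and, within a flip count, lexicographically by the flipped id
#' set. Unknown labels are never flipped (they are unconstrained in the
#' filters anyway).
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param maxFlips maximum number of labels to flip (>= 0).
#' @return list of label assignments; each element has \code{labels} (named
#'   character id -> affection), \code{flipCount} and \code{flippedIds}.
#' @export
enumerateRelabelings <- function(ped, maxFlips) {
  if (length(maxFlips) != 1 || is.na(maxFlips) || maxFlips < 0)
    stop("maxFlips must be a single nonnegative integer")
  base <- affectionLabels(ped)
  soft <- .flippableIds(ped)
  maxFlips <- min(maxFlips, length(soft))
  out <- list(list(labels = base, flipCount = 0L,
                   flippedIds = character()))
  if (maxFlips >= 1) {
    for (k in seq_len(maxFlips)) {
      sets <- combn(soft, k, simplify = FALSE)  # lexicographic: soft is sorted
      out <- c(out, lapply(sets, function(ids) list(
        labels = .flipAffection(base, ids),
        flipCount = as.integer(k), flippedIds = ids)))
    }
  }
  out
}

#' Number of relabelings without enumerating them
#' @param ped a \linkS4class{Pedigree}
#' @param maxFlips maximum flip count
#' @return sum over k of choose(s, k) for s soft sequenced labeled members
#' @export
countRelabelings <- function(ped, maxFlips) {
  s <- length(.flippableIds(ped))
  sum(choose(s, 0:min(maxFlips, s)))
}
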