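## Detection of frame-breaking indels (candidate frameshifts) in a
## codon-aware alignment, generalising the focal-site screen to the whole
## gene. The alignment's consensus defines the reference frame: a column
## where most sequences have gaps is an insertion column, one where most
## have residues is part of the frame.

#' Scan a codon-aware alignment for frame-breaking indels
#'
#' For each sequence, an insertion run is a maximal set of contiguous
#' columns where the sequence has residues but at least `min_support_frac`
#' of all sequences have gaps; a deletion run is a maximal contiguous gap
#' run over columns where at least `min_support_frac` of sequences have
#' residues. Runs whose length is not a multiple of 3 break the reading
#' frame and are reported as candidates, with the net frame offset
#' `length mod 3`. Runs covering `exclude_column` (e.g. the known focal
#' insertion) can be excluded to find "other" frameshifts.
#'
#' @param aln Character alignment matrix (>= 3 columns).
#' @param min_support_frac Consensus support fraction defining the frame
#'   (default 0.8).
#' @param exclude_column Optional 1-based column; candidate runs covering
#'   it are dropped.
#' @return Data frame sorted by column then taxon: `taxon`, `column`
#'   (1-based start of the run), `kind` (`insertion` / `deletion`),
#'   `run_length`, `frame_offset` (1 or 2).
#' @export
scan_frameshifts <- function(aln, min_support_frac = 0.8,
                             exclude_column = NULL) {
  check_alignment(aln)
  if (ncol(aln) < 3L) stop("input error: alignment shorter than one codon")
  if (!(min_support_frac > 0.5 && min_support_frac <= 1))
    stop("min_support_frac must lie in (0.5, 1]")
  gap_frac <- colMeans(is_gap(aln))
  cons_gap <- gap_frac >= min_support_frac          # insertion columns
  cons_res <- (1 - gap_frac) >= min_support_frac    # frame columns
  res <- list()
  for (tx in rownames(aln)) {
    row_gap <- is_gap(aln[tx, ])
    for (kind in c("insertion", "deletion")) {
      mask <- if (kind == "insertion") !row_gap & cons_gap else
        row_gap & cons_res
      r <- rle(mask)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        len <- r$lengths[j]
        if (len %% 3L == 0L) next
        if (!is.null(exclude_column) &&
            exclude_column >= starts[j] && exclude_column <= ends[j]) next
        res[[length(res) + 1L]] <- data.frame(
          taxon = tx, column = starts[j], kind = kind,
          run_length = len, frame_offset = len %% 3L,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(taxon = character(), column = integer(), kind = character(),
               run_length = integer(), frame_offset = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(out$column, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a MACSE-style FASTA with "!" frameshift marks
#'
#' Convenience importer for codon-aware aligners that mark frameshift
#' positions with `!`. The marks are recorded per taxon and replaced by
#' gaps in the returned alignment.
#'
#' @param path Path to the FASTA file.
#' @return List with `alignment` (character matrix) and `marks`
#'   (data frame `taxon`, `column` of "!" positions).
#' @export
read_macse_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("FASTA format error: no records in ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  names(seqs) <- ids
  m <- strings_to_alignment(seqs)
  bang <- which(m == "!", arr.ind = TRUE)
  marks <- data.frame(taxon = rownames(m)[bang[, 1L]],
                      column = unname(bang[, 2L]),
                      stringsAsFactors = FALSE)
  marks <- marks[order(marks$taxon, marks$column), , drop = FALSE]
  rownames(marks) <- NULL
  m[m == "!"] <- "-"
  bad <- !(m %in% DNA_ALPHABET)
  if (any(bad)) stop("alphabet error: illegal character(s) ",
                     paste(unique(m[matrix(bad, nrow(m))]), collapse = ", "))
  list(alignment = m, marks = marks)
}
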