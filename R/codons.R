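## Codon usage around the insertion in the shifted (0) and corrected (+1)
## reading frames under the vertebrate mitochondrial genetic code
## (translation table 2: AGA/AGG are stops, ATA is Met, TGA is Trp), and
## the premature-stop scan for read-through of the insertion.

## memoised codon -> amino acid map for a seqinr numcode
codon_env <- new.env(parent = emptyenv())
genetic_code_table <- function(numcode = 2L) {
  key <- as.character(numcode)
  if (is.null(codon_env[[key]])) {
    cods <- as.vector(outer(outer(NUCLEOTIDES, NUCLEOTIDES, paste0),
                            NUCLEOTIDES, paste0))
    aa <- vapply(cods, function(cd)
      seqinr::translate(tolower(strsplit(cd, "")[[1L]]), numcode = numcode),
      character(1))
    codon_env[[key]] <- stats::setNames(aa, cods)
  }
  codon_env[[key]]
}

## standard physico-chemical classes by one-letter amino acid code
AA_CLASS <- c(A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
              P = "nonpolar", F = "nonpolar", W = "nonpolar", M = "nonpolar",
              G = "nonpolar",
              S = "polar", T = "polar", C = "polar", Y = "polar",
              N = "polar", Q = "polar",
              K = "basic", R = "basic", H = "basic",
              D = "acidic", E = "acidic",
              "*" = "stop")

#' Translate a codon under a genetic code
#' @param codon Character vector of 3-letter codons over \{A, C, G, T\}.
#' @param numcode NCBI translation table (default 2, vertebrate
#'   mitochondrial).
#' @return One-letter amino acids (`"*"` for stops).
#' @export
translate_codon <- function(codon, numcode = 2L) {
  tab <- genetic_code_table(numcode)
  unname(tab[toupper(codon)])
}

## slot column indices around the focal insertion column
frame_slot_columns <- function(focal, frame) {
  focal <- as.integer(focal)
  if (frame == 0L) {
    list("insertion codon" = (focal - 2L):focal,
         "following codon 1" = (focal + 1L):(focal + 3L),
         "following codon 2" = (focal + 4L):(focal + 6L))
  } else {
    ## +1 corrected frame: the nucleotide right after the insertion
    ## (A-175 in the reference numbering) is skipped
    list("insertion codon" = (focal - 2L):focal,
         "following codon 1" = (focal + 2L):(focal + 4L),
         "following codon 2" = (focal + 5L):(focal + 7L))
  }
}

#' Extract the codons around the insertion for one sequence row
#'
#' Frame 0 (shifted, insertion read through) uses columns
#' `focal-2..focal`, `focal+1..focal+3`, `focal+4..focal+6`; frame +1
#' (corrected) skips the nucleotide immediately after the insertion and
#' uses `focal-2..focal`, `focal+2..focal+4`, `focal+5..focal+7`. The
#' insertion-codon slot is identical in both frames by construction. A slot
#' containing a gap is dropped (`NA`) with a warning.
#'
#' @param row Character vector (one alignment row) or a single string.
#' @param focal 1-based focal column (default 174).
#' @param frame 0 or 1.
#' @return Named character vector of three codons (`NA` for dropped slots).
#' @export
extract_frame_codons <- function(row, focal = 174L, frame = 0L) {
  if (length(row) == 1L && nchar(row) > 1L)
    row <- strsplit(toupper(row), "")[[1L]]
  frame <- as.integer(frame)
  if (!frame %in% c(0L, 1L)) stop("frame must be 0 or 1")
  slots <- frame_slot_columns(focal, frame)
  hi <- max(unlist(slots)); lo <- min(unlist(slots))
  if (lo < 1L || hi > length(row))
    stop("coordinate error: slot columns [", lo, ", ", hi,
         "] outside the sequence (length ", length(row), ")")
  out <- vapply(slots, function(idx) {
    cd <- row[idx]
    if (any(is_gap(cd))) NA_character_ else paste(cd, collapse = "")
  }, character(1))
  if (anyNA(out))
    warning("slot(s) containing a gap dropped: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Codon frequency table around the insertion
#'
#' Tallies the three codon slots (insertion codon and the two following
#' codons) over the carrier taxa in the requested reading frame. Slots
#' containing a gap are skipped per row; codons containing `N` are removed
#' before normalisation. Each codon is annotated with its amino acid and
#' physico-chemical class under the vertebrate mitochondrial code.
#'
#' @param aln Character alignment matrix.
#' @param carriers Taxa with the insertion (subset of rownames).
#' @param frame 0 (shifted) or 1 (corrected).
#' @param focal 1-based focal column (default 174).
#' @param include_upstream Also tally the three codons upstream of the
#'   insertion codon (columns `focal-11 .. focal-3`), identical in both
#'   frames (default `FALSE`).
#' @param numcode Genetic code (default 2).
#' @return Long data frame: `frame`, `slot`, `codon`, `count`, `freq`,
#'   `aa`, `aa_class`.
#' @export
codon_frequencies <- function(aln, carriers, frame = 0L, focal = 174L,
                              include_upstream = FALSE, numcode = 2L) {
  check_alignment(aln)
  miss <- setdiff(carriers, rownames(aln))
  if (length(miss)) stop("carriers not in alignment: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  focal <- as.integer(focal)
  slots <- frame_slot_columns(focal, as.integer(frame))
  if (include_upstream) {
    up <- list("upstream codon 1" = (focal - 11L):(focal - 9L),
               "upstream codon 2" = (focal - 8L):(focal - 6L),
               "upstream codon 3" = (focal - 5L):(focal - 3L))
    slots <- c(up, slots)
  }
  tab <- genetic_code_table(numcode)
  rows <- lapply(names(slots), function(slot) {
    idx <- slots[[slot]]
    if (min(idx) < 1L || max(idx) > ncol(aln))
      stop("coordinate error: slot '", slot, "' outside the alignment")
    sub <- aln[carriers, idx, drop = FALSE]
    cods <- apply(sub, 1L, paste, collapse = "")
    cods <- cods[!grepl("[-N]", cods)]   # gap slots skipped, N codons removed
    if (length(cods) == 0L) {
      warning("no usable codons in slot '", slot, "'")
      return(NULL)
    }
    tt <- sort(table(cods), decreasing = TRUE)
    data.frame(frame = ifelse(frame == 0L, "0", "+1"), slot = slot,
               codon = names(tt), count = as.integer(tt),
               freq = as.numeric(tt) / sum(tt),
               aa = unname(tab[names(tt)]),
               aa_class = unname(AA_CLASS[tab[names(tt)]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Find the first in-frame stop when the insertion is read through
#'
#' Translates an ungapped coding sequence from its first position in codon
#' steps and returns the 1-based position of the last base of the first
#' stop codon (TAA, TAG, AGA, AGG under the vertebrate mitochondrial code),
#' or `NA` if no stop occurs. For an ND3 sequence that retains the +1
#' insertion this locates the premature termination of the read-through
#' product.
#'
#' @param seq Character vector or single string; gaps are removed.
#' @param numcode Genetic code (default 2).
#' @return Integer bp position of the end of the first stop codon, or
#'   `NA_integer_` ("none").
#' @export
premature_stop_scan <- function(seq, numcode = 2L) {
  if (length(seq) == 1L && nchar(seq) > 1L)
    seq <- strsplit(toupper(seq), "")[[1L]]
  seq <- seq[!is_gap(seq)]
  if (length(seq) < 3L) stop("input error: sequence shorter than one codon")
  tab <- genetic_code_table(numcode)
  n_cod <- length(seq) %/% 3L
  for (i in seq_len(n_cod)) {
    cd <- paste(seq[(3L * i - 2L):(3L * i)], collapse = "")
    aa <- tab[cd]             # NA for codons containing N: not a stop call
    if (!is.na(aa) && aa == "*") return(3L * i)
  }
  NA_integer_
}
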