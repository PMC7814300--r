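## Shared constants and small helpers.

DNA_ALPHABET <- c("A", "C", "G", "T", "N", "-")
NUCLEOTIDES <- c("A", "C", "G", "T")
STATES5 <- c("GAP", "A", "C", "G", "T")
STATES2 <- c("absent", "present")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' State alphabet for the k-state insertion character
#'
#' The 2-state encoding distinguishes absence vs presence of the insertion;
#' the 5-state encoding distinguishes the gap and the four inserted
#' nucleotides.
#'
#' @param k Number of states, 2 or 5.
#' @return Character vector of state labels.
#' @export
state_levels <- function(k) {
  if (identical(as.integer(k), 2L)) return(STATES2)
  if (identical(as.integer(k), 5L)) return(STATES5)
  stop("only k = 2 or k = 5 state encodings are supported, got k = ", k)
}

#' Collapse 5-state insertion calls to the 2-state encoding
#'
#' @param states Character vector over \{GAP, A, C, G, T\} (or already binary).
#' @return Character vector over \{absent, present\}.
#' @export
collapse_states <- function(states) {
  out <- ifelse(states %in% c("GAP", "absent"), "absent", "present")
  names(out) <- names(states)
  out
}

## internal: deterministic node names for a phylo object: tips keep their
## labels, internal nodes are named by their ape node index.
node_names <- function(tree) {
  c(tree$tip.label, paste0("N", seq.int(ape::Ntip(tree) + 1L,
                                        ape::Ntip(tree) + tree$Nnode)))
}

is_gap <- function(x) x == "-"

## internal: validate a character alignment matrix
check_alignment <- function(aln) {
  if (!is.matrix(aln) || !is.character(aln))
    stop("alignment must be a character matrix (taxa in rows)")
  if (is.null(rownames(aln)) || anyDuplicated(rownames(aln)))
    stop("alignment rows must carry unique taxon identifiers")
  if (ncol(aln) < 1L) stop("alignment must have at least one column")
  invisible(aln)
}

## internal: alignment matrix from a named character vector of strings
strings_to_alignment <- function(x) {
  stopifnot(!is.null(names(x)))
  chars <- strsplit(toupper(x), "", fixed = TRUE)
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L)
    stop("alignment-shape error: sequences differ in length")
  m <- do.call(rbind, chars)
  rownames(m) <- names(x)
  m
}

alignment_to_strings <- function(aln) {
  stats::setNames(apply(aln, 1L, paste, collapse = ""), rownames(aln))
}
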