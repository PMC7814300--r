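## Readers/writers for the standard formats the pipeline touches, and
## identifier reconciliation between alignment and tree.

#' Read a FASTA multiple alignment
#'
#' Sequences are upper-cased and returned as a character matrix with one row
#' per taxon and one column per alignment position (1-based coordinates
#' throughout the package). The permitted alphabet is \code{A C G T N -};
#' IUPAC ambiguity codes other than \code{N} are mapped to \code{N} with a
#' warning, any other character is an error naming the offending taxon and
#' column.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return Character matrix (taxa x columns) with unique rownames.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE,
                       as.string = FALSE),
    error = function(e) stop("FASTA format error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(recs) == 0L) stop("FASTA format error: no records in ", path)
  nm <- names(recs)
  if (anyDuplicated(nm))
    stop("duplicate taxon identifiers in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L)
    stop("alignment-shape error: records have unequal lengths (",
         paste(range(lens), collapse = "-"), ")")
  m <- matrix(toupper(unlist(lapply(recs, as.character), use.names = FALSE)),
              nrow = length(recs), byrow = TRUE)
  rownames(m) <- nm
  ambig <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  hit <- m %in% ambig
  if (any(hit)) {
    warning(sum(hit), " IUPAC ambiguity code(s) other than N mapped to N")
    m[matrix(hit, nrow(m))] <- "N"
  }
  bad <- matrix(!(m %in% DNA_ALPHABET), nrow(m))
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    stop("alphabet error: illegal character '", m[ij[1L], ij[2L]],
         "' in taxon '", nm[ij[1L]], "' at column ", ij[2L])
  }
  m
}

#' Write an alignment matrix to FASTA
#'
#' Records are written in input (row) order, one sequence line per record, so
#' a write/read round trip reproduces records exactly.
#'
#' @param aln Character alignment matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  check_alignment(aln)
  s <- alignment_to_strings(aln)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0(">", names(s), "\n", s), con, sep = "\n")
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Polytomies are permitted; an unrooted basal trifurcation is accepted and
#' treated as rooted at the basal node. If the tree carries no branch lengths
#' at all, every edge length is set to 1.0 (the equal-branch-lengths
#' convention used for trees derived from taxonomy syntheses); a tree with
#' only some lengths is rejected.
#'
#' @param path Path to a file holding a single Newick tree, or a literal
#'   Newick string (must contain "(" and end in ";").
#' @return An [ape::phylo] object with edge lengths on every edge.
#' @export
read_newick <- function(path) {
  txt <- path
  if (!grepl("\\(", path)) {
    if (!file.exists(path)) stop("Newick file not found: ", path)
    txt <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  tr <- withCallingHandlers(
    tryCatch(ape::read.tree(text = txt),
             error = function(e) NULL),
    warning = function(w) invokeRestart("muffleWarning"))
  if (is.null(tr) || inherits(tr, "multiPhylo") && length(tr) != 1L)
    stop("Newick parse error (unbalanced parentheses or malformed tree)")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (!inherits(tr, "phylo") || ape::Ntip(tr) < 2L)
    stop("Newick parse error: need a single tree with >= 2 tips")
  if (anyDuplicated(tr$tip.label))
    stop("identifier error: duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(1, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    stop("branch-length error: some but not all edges carry lengths")
  }
  if (any(tr$edge.length < 0))
    stop("branch-length error: negative edge length")
  tr
}

#' Write a phylogeny to Newick
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read / write a taxon-state table
#'
#' TSV with header `taxon<TAB>state`; states must be in
#' \{GAP, A, C, G, T\} or \{absent, present\}.
#'
#' @param path Path to the TSV.
#' @param focal Focal alignment column the states refer to (stored as an
#'   attribute; default 174).
#' @return Data frame with columns `taxon` and `state`.
#' @export
read_state_table <- function(path, focal = 174L) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("taxon", "state") %in% names(df)))
    stop("state table must have columns 'taxon' and 'state'")
  new_state_table(df$taxon, df$state, focal)
}

#' @rdname read_state_table
#' @param states A state table as returned by [call_states()].
#' @export
write_state_table <- function(states, path) {
  utils::write.table(states[, c("taxon", "state")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## internal constructor with validation
new_state_table <- function(taxa, states, focal) {
  ok <- states %in% STATES5 | states %in% STATES2
  if (!all(ok))
    stop("illegal state(s): ", paste(unique(states[!ok]), collapse = ", "))
  if (anyDuplicated(taxa))
    stop("duplicate taxa in state table: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  out <- data.frame(taxon = as.character(taxa), state = as.character(states),
                    stringsAsFactors = FALSE)
  attr(out, "focal") <- as.integer(focal)
  out
}

#' Reconcile taxa between a state table (or alignment) and a tree
#'
#' Takes the intersection of taxon sets, prunes the tree to the shared tips
#' (degree-2 internal nodes created by pruning are suppressed with their edge
#' lengths summed, as [ape::keep.tip] does), subsets the data to the same
#' taxa, and reports what was dropped on each side.
#'
#' @param x A state table (data frame with `taxon`) or an alignment matrix.
#' @param tree A `phylo` object.
#' @return List with elements `data`, `tree`, `dropped_from_data`,
#'   `dropped_from_tree`.
#' @export
reconcile <- function(x, tree) {
  taxa <- if (is.matrix(x)) rownames(x) else x$taxon
  shared <- intersect(taxa, tree$tip.label)
  if (length(shared) < 2L)
    stop("insufficient-overlap error: fewer than 2 taxa shared between ",
         "data (", length(taxa), ") and tree (", length(tree$tip.label), ")")
  dropped_data <- setdiff(taxa, shared)
  dropped_tree <- setdiff(tree$tip.label, shared)
  tr <- if (length(dropped_tree)) ape::keep.tip(tree, shared) else tree
  out_x <- if (is.matrix(x)) {
    x[rownames(x) %in% shared, , drop = FALSE]
  } else {
    y <- x[x$taxon %in% shared, , drop = FALSE]
    rownames(y) <- NULL
    attr(y, "focal") <- attr(x, "focal")
    y
  }
  list(data = out_x, tree = tr,
       dropped_from_data = dropped_data, dropped_from_tree = dropped_tree)
}
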