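## Alignment QC filters and calling of the focal-column insertion state.

#' Remove low-occupancy alignment columns
#'
#' Columns whose non-gap occupancy is below `min_frac` of the records are
#' deleted; this removes insertions seen only in a small proportion of taxa.
#' `N` counts as present (it is a residue observation, not a gap). The
#' boundary is inclusive: a column present in exactly `min_frac` of records
#' is kept.
#'
#' @param aln Character alignment matrix.
#' @param min_frac Minimum fraction of records with a residue (default 0.05).
#' @return List with `alignment` (filtered), `removed_columns` (old 1-based
#'   indices) and `column_map` (old -> new 1-based index, `NA` for removed
#'   columns) so a focal position can be re-located after filtering.
#' @export
filter_columns <- function(aln, min_frac = 0.05) {
  check_alignment(aln)
  if (!(min_frac > 0 && min_frac <= 1))
    stop("min_frac must be in (0, 1]")
  occupancy <- colMeans(!is_gap(aln))
  keep <- occupancy >= min_frac
  if (!any(keep)) stop("empty-alignment error: all columns removed")
  map <- rep(NA_integer_, ncol(aln))
  map[keep] <- seq_len(sum(keep))
  list(alignment = aln[, keep, drop = FALSE],
       removed_columns = which(!keep),
       column_map = map)
}

#' Drop taxa with low-quality flanks around the focal column
#'
#' Removes any record containing a gap or an `N` in the two codons (six
#' alignment columns) immediately upstream or downstream of the focal
#' column. The focal column itself is not examined — a gap there is the
#' legitimate "insertion absent" state — except that an `N` exactly at the
#' focal column also drops the record, since presence/absence cannot then be
#' determined.
#'
#' @param aln Character alignment matrix.
#' @param focal 1-based focal column; `focal - 6` and `focal + 6` must lie
#'   within the alignment.
#' @return List with `kept` (filtered alignment) and `dropped` (data frame
#'   of taxon and reason).
#' @export
qc_filter_taxa <- function(aln, focal) {
  check_alignment(aln)
  focal <- as.integer(focal)
  if (focal - 6L < 1L || focal + 6L > ncol(aln))
    stop("coordinate error: focal window [", focal - 6L, ", ", focal + 6L,
         "] outside alignment columns 1..", ncol(aln))
  win <- c((focal - 6L):(focal - 1L), (focal + 1L):(focal + 6L))
  bad_flank <- apply(aln[, win, drop = FALSE], 1L,
                     function(r) any(r %in% c("-", "N")))
  bad_focal <- aln[, focal] == "N"
  drop <- bad_flank | bad_focal
  reason <- ifelse(bad_flank, "gap or N in flanking codons", "N at focal column")
  list(kept = aln[!drop, , drop = FALSE],
       dropped = data.frame(taxon = rownames(aln)[drop],
                            reason = reason[drop],
                            stringsAsFactors = FALSE))
}

#' Call each taxon's state at the focal column
#'
#' A gap at the focal column is the state `GAP` (insertion absent); a
#' nucleotide is the insertion present as that nucleotide. Flank QC
#' ([qc_filter_taxa]) is re-applied internally unless `qc = FALSE`.
#'
#' @param aln Character alignment matrix.
#' @param focal 1-based focal column (default 174).
#' @param qc Re-apply [qc_filter_taxa] before calling (default `TRUE`).
#' @return A state table: data frame with columns `taxon`, `state` and a
#'   `focal` attribute.
#' @export
call_states <- function(aln, focal = 174L, qc = TRUE) {
  check_alignment(aln)
  focal <- as.integer(focal)
  if (qc) aln <- qc_filter_taxa(aln, focal)$kept
  if (focal < 1L || focal > ncol(aln))
    stop("coordinate error: focal column ", focal, " outside alignment")
  ch <- aln[, focal]
  if (any(ch == "N"))
    stop("N at focal column after QC; run qc_filter_taxa first")
  st <- ifelse(is_gap(ch), "GAP", ch)
  new_state_table(rownames(aln), st, focal)
}
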