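## Per-position nucleotide frequencies, Shannon entropy H, information
## content R = log2(4) - H, sequence-logo heights, and the windowed
## rank-sum comparison between carrier and non-carrier groups.

#' Per-column nucleotide frequencies
#'
#' Gaps and `N` are excluded from both numerator and denominator, so a
#' gap-rich column never masquerades as conserved; per-column coverage (the
#' number of A/C/G/T observations) is reported alongside. Columns with zero
#' coverage get `NA` frequencies.
#'
#' @param aln Character alignment matrix.
#' @param taxa Optional subset of taxa (rownames); default all.
#' @return List with `freq` (positions x 4 matrix over A, C, G, T),
#'   `counts` (same shape, integer) and `coverage` (integer vector).
#' @export
site_frequencies <- function(aln, taxa = NULL) {
  check_alignment(aln)
  if (!is.null(taxa)) {
    miss <- setdiff(taxa, rownames(aln))
    if (length(miss)) stop("taxa not in alignment: ",
                           paste(utils::head(miss, 5L), collapse = ", "))
    if (length(taxa) == 0L) stop("empty taxon subset")
    aln <- aln[taxa, , drop = FALSE]
  }
  counts <- vapply(NUCLEOTIDES, function(nt) colSums(aln == nt),
                   numeric(ncol(aln)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, NUCLEOTIDES))
  storage.mode(counts) <- "integer"
  coverage <- rowSums(counts)
  freq <- counts / coverage
  freq[coverage == 0L, ] <- NA_real_
  rownames(freq) <- rownames(counts) <- seq_len(ncol(aln))
  list(freq = freq, counts = counts, coverage = as.integer(coverage))
}

#' Shannon entropy of a nucleotide frequency vector
#'
#' `H = -sum(freq * log2(freq))` with `0 * log2(0)` defined as 0; lies in
#' `[0, 2]` bits for four states.
#'
#' @param freqs Numeric vector (or matrix with rows as positions) of
#'   non-negative frequencies summing to 1; `NA` rows give `NA`.
#' @return Entropy in bits (vector if a matrix was given).
#' @export
shannon_entropy <- function(freqs) {
  if (is.matrix(freqs))
    return(apply(freqs, 1L, shannon_entropy))
  if (anyNA(freqs)) return(NA_real_)
  if (any(freqs < 0)) stop("domain error: negative frequency")
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("frequencies must sum to 1, got ", sum(freqs))
  p <- freqs[freqs > 0]
  -sum(p * log2(p))
}

#' Information content of a nucleotide frequency vector
#'
#' `R = log2(4) - H`, ranging from 0 (uniform) to 2 bits at complete
#' conservation.
#'
#' @inheritParams shannon_entropy
#' @return Information content in bits.
#' @export
information_content <- function(freqs) {
  log2(4) - shannon_entropy(freqs)
}

#' Per-position conservation profile of a taxon group
#'
#' @param aln Character alignment matrix.
#' @param taxa Optional taxon subset defining the group.
#' @param group Group label (e.g. `"with insertion"`).
#' @return Data frame: `position`, `freq_A` .. `freq_T`, `coverage`, `H`,
#'   `R`, `group`; positions with zero coverage have `NA` for H and R
#'   (never 0).
#' @export
conservation_profile <- function(aln, taxa = NULL, group = NA_character_) {
  sf <- site_frequencies(aln, taxa)
  H <- shannon_entropy(sf$freq)
  out <- data.frame(position = seq_len(nrow(sf$freq)),
                    freq_A = sf$freq[, "A"], freq_C = sf$freq[, "C"],
                    freq_G = sf$freq[, "G"], freq_T = sf$freq[, "T"],
                    coverage = sf$coverage, H = H, R = log2(4) - H,
                    group = group,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_sequences") <- if (is.null(taxa)) nrow(aln) else length(taxa)
  out
}

## internal: R values of a profile inside a closed window of positions
window_R <- function(profile, window) {
  if (!all(window %in% profile$position))
    stop("coordinate error: window [", window[1], ", ",
         window[length(window)], "] not covered by the profile")
  profile$R[match(window, profile$position)]
}

#' Compare information content between groups in a window
#'
#' Two-sided Wilcoxon rank-sum test on the per-position information-content
#' values of the two groups inside the window, plus a relative difference:
#' `percent_difference = (mean R_with - mean R_without) / mean R_with * 100`
#' (how much lower the without-insertion group is, as a percentage of the
#' with-insertion mean).
#'
#' @param profile_with,profile_without Profiles from
#'   [conservation_profile()].
#' @param window Length-2 vector of 1-based positions, inclusive (default
#'   `c(163, 180)`).
#' @return List: `percent_difference`, `statistic` (rank-sum W), `p_value`,
#'   `n_positions`, `mean_R_with`, `mean_R_without`, `definition`.
#' @export
compare_windows <- function(profile_with, profile_without,
                            window = c(163L, 180L)) {
  pos <- seq.int(window[1L], window[2L])
  rw <- window_R(profile_with, pos)
  rwo <- window_R(profile_without, pos)
  ## positions with undefined R (zero coverage, e.g. the focal column in
  ## the gap group) are excluded from the comparison
  rw <- rw[!is.na(rw)]
  rwo <- rwo[!is.na(rwo)]
  if (!length(rw) || !length(rwo))
    stop("no covered positions in the window for one of the groups")
  wt <- suppressWarnings(stats::wilcox.test(rw, rwo,
                                            alternative = "two.sided"))
  p <- wt$p.value
  if (is.nan(p)) p <- 1   # every value tied across both groups
  mw <- mean(rw); mwo <- mean(rwo)
  list(percent_difference = (mw - mwo) / mw * 100,
       statistic = unname(wt$statistic),
       p_value = p,
       n_positions = length(pos),
       n_used_with = length(rw), n_used_without = length(rwo),
       mean_R_with = mw, mean_R_without = mwo,
       definition = paste("(mean R_with - mean R_without) / mean R_with",
                          "* 100; two-sided Wilcoxon rank-sum on",
                          "per-position R"))
}

#' Sequence-logo height matrix
#'
#' Per position and nucleotide, `height = freq * R`, so column heights sum
#' to the position's information content (maximum 2 bits at complete
#' conservation, all-zero at a uniform column).
#'
#' @param profile A [conservation_profile()] data frame.
#' @param window Length-2 position window, inclusive (default
#'   `c(163, 181)`).
#' @return Matrix positions x \{A, C, G, T\} of heights in bits.
#' @export
logo_matrix <- function(profile, window = c(163L, 181L)) {
  pos <- seq.int(window[1L], window[2L])
  if (!all(pos %in% profile$position))
    stop("coordinate error: window not covered by the profile")
  rows <- match(pos, profile$position)
  freq <- as.matrix(profile[rows, c("freq_A", "freq_C", "freq_G", "freq_T")])
  heights <- freq * profile$R[rows]
  dimnames(heights) <- list(pos, NUCLEOTIDES)
  heights
}
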