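test_that("site frequencies exclude gaps and N from the census", {
  m <- aln_fix(a = "AAG", b = "ACA", c = "A-C", d = "ANT")
  sf <- site_frequencies(m)
  expect_equal(unname(sf$freq[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(sf$freq[2, ]), c(0.5, 0.5, 0, 0))
  expect_equal(sf$coverage, c(4L, 2L, 4L))
  ## zero-coverage column: NA frequencies, never zeros
  m2 <- aln_fix(a = "A-", b = "A-")
  sf2 <- site_frequencies(m2)
  expect_true(all(is.na(sf2$freq[2, ])))
  expect_true(is.na(shannon_entropy(sf2$freq[2, ])))
})

test_that("random alignments match a brute-force per-column census", {
  withr::local_seed(88)
  m <- matrix(sample(c("A", "C", "G", "T", "N", "-"), 200, TRUE), 8, 25,
              dimnames = list(paste0("s", 1:8), NULL))
  sf <- site_frequencies(m)
  ref <- census_frequencies(m)
  expect_equal(unname(sf$freq), unname(ref$freq))
  expect_equal(sf$coverage, ref$coverage)
  ## subsetting works the same way
  sub <- c("s1", "s3", "s8")
  expect_equal(unname(site_frequencies(m, sub)$freq),
               unname(census_frequencies(m, sub)$freq))
})

test_that("entropy and information content follow the closed forms", {
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(c(0.5, 0.5, 0, 0)), 1)
  expect_equal(information_content(c(1, 0, 0, 0)), 2)
  expect_equal(information_content(rep(0.25, 4)), 0)
  expect_error(shannon_entropy(c(-0.1, 1.1, 0, 0)), "domain error")
  ## R + H = 2 and permutation invariance, on a frequency grid
  withr::local_seed(12)
  for (i in 1:20) {
    f <- stats::runif(4); f <- f / sum(f)
    expect_equal(shannon_entropy(f) + information_content(f), 2)
    expect_equal(shannon_entropy(f), shannon_entropy(sample(f)))
    expect_lte(shannon_entropy(f), 2)
  }
})

## profile rows with chosen per-position R (frequencies are irrelevant to
## the window comparison, which works on R alone)
profile_from_R <- function(R_values, start = 163L) {
  n <- length(R_values)
  data.frame(position = seq(start, length.out = n),
             freq_A = NA_real_, freq_C = NA_real_,
             freq_G = NA_real_, freq_T = NA_real_,
             coverage = 100L,
             H = 2 - R_values, R = R_values, group = "x",
             stringsAsFactors = FALSE)
}

## profile rows from explicit frequency vectors (for the logo)
profile_from_freqs <- function(freq_rows, start = 163L) {
  f <- do.call(rbind, freq_rows)
  H <- apply(f, 1, shannon_entropy)
  data.frame(position = seq(start, length.out = nrow(f)),
             freq_A = f[, 1], freq_C = f[, 2],
             freq_G = f[, 3], freq_T = f[, 4],
             coverage = 100L, H = H, R = 2 - H, group = "x",
             stringsAsFactors = FALSE)
}

test_that("identical profiles give zero difference and p near 1", {
  pr <- profile_from_R(rep(1.3, 18))
  cmp <- compare_windows(pr, pr, c(163, 180))
  expect_equal(cmp$percent_difference, 0)
  expect_gt(cmp$p_value, 0.9)
})

test_that("a 2-vs-1-bit window is 50% lower with p below 1e-3", {
  cmp <- compare_windows(profile_from_R(rep(2, 18)),
                         profile_from_R(rep(1, 18)), c(163, 180))
  expect_equal(cmp$percent_difference, 50)
  expect_lt(cmp$p_value, 1e-3)
  expect_error(compare_windows(profile_from_R(rep(2, 18)),
                               profile_from_R(rep(1, 18)), c(163, 200)),
               "coordinate error")
})

test_that("the rank-sum statistic matches a brute-force rank computation", {
  withr::local_seed(19)
  for (i in 1:10) {
    r1 <- stats::runif(18, 0, 2)
    r2 <- stats::runif(18, 0, 2)
    cmp <- compare_windows(profile_from_R(r1), profile_from_R(r2))
    rk <- rank(c(r1, r2))
    W_ref <- sum(rk[1:18]) - 18 * 19 / 2   # Mann-Whitney U of group 1
    expect_equal(cmp$statistic, W_ref)
  }
})

test_that("the rank-sum p-value matches a permutation test", {
  withr::local_seed(23)
  r1 <- stats::runif(15, 1.2, 2)
  r2 <- stats::runif(15, 0.8, 1.9)
  cmp <- compare_windows(profile_from_R(r1), profile_from_R(r2),
                         c(163, 177))
  pool <- c(r1, r2)
  obs <- abs(mean(rank(pool)[1:15]) - mean(rank(pool)[16:30]))
  perm <- replicate(1000, {
    idx <- sample(30, 15)
    rk <- rank(pool)
    abs(mean(rk[idx]) - mean(rk[-idx]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(cmp$p_value - p_perm), 0.05)
})

test_that("logo heights are freq * R and sum to R per column", {
  pr <- profile_from_freqs(list(c(0, 1, 0, 0),        # conserved C
                                rep(0.25, 4),         # uniform
                                c(0.5, 0.5, 0, 0)),   # R = 1
                           start = 163L)
  lm <- logo_matrix(pr, c(163, 165))
  expect_equal(unname(lm["163", ]), c(0, 2, 0, 0))    # conserved C: 2 bits
  expect_equal(unname(lm["164", ]), rep(0, 4))        # uniform: all zero
  expect_equal(unname(lm["165", ]), c(0.5, 0.5, 0, 0))  # two heights of 0.5
  expect_equal(unname(rowSums(lm)), pr$R)
})
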