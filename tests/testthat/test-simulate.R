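test_that("Yule trees are deterministic, binary and sized correctly", {
  expect_error(simulate_yule_tree(1, seed = 1), "parameter error")
  t2 <- simulate_yule_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2L)          # a single cherry
  expect_equal(t2$Nnode, 1L)
  a <- simulate_yule_tree(50, seed = 9)
  b <- simulate_yule_tree(50, seed = 9)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  big <- simulate_yule_tree(100, seed = 10)
  expect_equal(big$Nnode, 99L)             # 2n - 1 nodes on a binary tree
  expect_true(ape::is.binary.phylo(big))
  poly <- simulate_yule_tree(40, seed = 11, polytomy_tol = 0.05)
  expect_lt(poly$Nnode, 39L)               # some nodes collapsed
})

test_that("trait simulation records a truth that matches its own census", {
  tr <- simulate_yule_tree(30, seed = 12)
  sim <- simulate_er_states(tr, k = 5L, q = 0.2, seed = 13)
  expect_equal(sort(unique(sim$states$taxon)), sort(tr$tip.label))
  ns <- sim$truth$node_states
  edge <- tr$edge
  nn <- nd3shift:::node_names(tr)
  census <- sum(ns[nn[edge[, 1]]] != ns[nn[edge[, 2]]])
  expect_equal(nrow(sim$truth$events), census)
  ## q = 0: everything inherits the root state, zero events
  sim0 <- simulate_er_states(tr, k = 5L, q = 0, seed = 14)
  expect_equal(length(unique(sim0$truth$node_states)), 1L)
  expect_equal(nrow(sim0$truth$events), 0L)
  ## determinism
  simA <- simulate_er_states(tr, k = 2L, q = 0.3, seed = 15)
  simB <- simulate_er_states(tr, k = 2L, q = 0.3, seed = 15)
  expect_identical(simA, simB)
})

test_that("saturated rates give uniform tip states", {
  tr <- simulate_yule_tree(2500, seed = 16)
  tr$edge.length <- rep(50, nrow(tr$edge))
  sim <- simulate_er_states(tr, k = 5L, q = 10, seed = 17)
  tab <- table(factor(sim$states$state, levels = state_levels(5)))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("cherry tip mismatch frequency matches the ER closed form", {
  ## two tips joined by a path of length 2t differ with probability
  ## (k-1)/k * (1 - exp(-k*q*2t)); check the empirical rate on many
  ## seeded cherries against a 3-standard-error band
  k <- 2; q <- 0.3; t <- 1
  n_rep <- 4000
  tr <- read_newick("(A:1,B:1);")
  p_theory <- (k - 1) / k * (1 - exp(-k * q * 2 * t))
  mism <- vapply(seq_len(n_rep), function(i) {
    s <- simulate_er_states(tr, k = k, q = q, seed = 5000 + i)$states
    s$state[1] != s$state[2]
  }, logical(1))
  se <- sqrt(p_theory * (1 - p_theory) / n_rep)
  expect_lt(abs(mean(mism) - p_theory), 3 * se)
})

test_that("ND3-like alignments honour the motif and are reproducible", {
  states <- data.frame(taxon = paste0("s", 1:20),
                       state = c(rep("C", 12), rep("T", 2), rep("GAP", 6)))
  a1 <- simulate_nd3_alignment(states, seed = 31, motif_fidelity = 1)
  a2 <- simulate_nd3_alignment(states, seed = 31, motif_fidelity = 1)
  expect_identical(a1, a2)
  aln <- a1$alignment
  expect_equal(ncol(aln), 355L)
  ## carriers carry their nucleotide at the focal column, non-carriers a gap
  expect_equal(unname(aln[c("s1", "s13", "s15"), 174]), c("C", "T", "-"))
  ## full conservation downstream of the insertion in carriers: R = 2
  carriers <- paste0("s", 1:14)
  prof <- conservation_profile(aln, carriers)
  expect_equal(prof$R[175:180], rep(2, 6))
  ## state calling recovers the simulated states exactly
  st <- call_states(aln, focal = 174)
  expect_equal(stats::setNames(st$state, st$taxon),
               stats::setNames(ifelse(states$state == "GAP", "GAP",
                                      states$state), states$taxon))
})

test_that("2-state carriers get a C insertion by convention", {
  states <- data.frame(taxon = c("x", "y"), state = c("present", "absent"))
  nd3 <- simulate_nd3_alignment(states, seed = 41)
  expect_equal(unname(nd3$alignment["x", 174]), "C")
  expect_equal(unname(nd3$alignment["y", 174]), "-")
})

test_that("planted insertions shift the focal column in the manifest", {
  states <- data.frame(taxon = paste0("s", 1:10),
                       state = c(rep("C", 8), "GAP", "GAP"))
  plant <- data.frame(taxon = "s9", column = 50L, kind = "insertion",
                      length = 1L, stringsAsFactors = FALSE)
  nd3 <- simulate_nd3_alignment(states, seed = 51, plant_indels = plant)
  expect_equal(nd3$manifest$focal, 175L)
  expect_equal(ncol(nd3$alignment), 356L)
  st <- call_states(nd3$alignment, focal = nd3$manifest$focal)
  expect_equal(st$state[st$taxon == "s1"], "C")
})
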