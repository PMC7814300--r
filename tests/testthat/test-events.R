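test_that("state changes are classified as gain/loss/transition/transversion", {
  expect_equal(classify_event("GAP", "C"), "gain")
  expect_equal(classify_event("T", "GAP"), "loss")
  expect_equal(classify_event("C", "T"), "transition")   # both pyrimidines
  expect_equal(classify_event("A", "G"), "transition")   # both purines
  expect_equal(classify_event("C", "G"), "transversion")
  expect_equal(classify_event("absent", "present"), "gain")
  expect_equal(classify_event("present", "absent"), "loss")
  expect_error(classify_event("C", "C"), "logic error")
})

## small fixture: 2-tip tree with hand-set posteriors
two_tip_post <- function(p_parent, s_parent, p_child, s_child) {
  tr <- read_newick("(X:1,Y:1);")
  lv <- state_levels(5)
  post <- matrix(0, 3, 5, dimnames = list(c("X", "Y", "N3"), lv))
  post["X", s_child] <- 1
  post["Y", "GAP"] <- 1
  post["N3", ] <- (1 - p_parent) / 4
  post["N3", s_parent] <- p_parent
  post["X", ] <- (1 - p_child) / 4 * (post["X", ] == 0) +
    p_child * (post["X", ] != 0)
  list(tree = tr, post = post)
}

test_that("the >= 0.90 evidence rule gates ML transition counting", {
  f <- two_tip_post(0.95, "GAP", 0.93, "C")
  ev <- count_transitions_ml(f$tree, f$post)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$category, "gain")
  expect_equal(ev$from, "GAP"); expect_equal(ev$to, "C")

  ## ambiguous parent: no event even with a confident child
  f2 <- two_tip_post(0.85, "GAP", 0.99, "C")
  expect_equal(nrow(count_transitions_ml(f2$tree, f2$post)), 0L)

  expect_error(count_transitions_ml(f$tree, f$post, threshold = 0.4),
               "parameter error")
  expect_error(count_transitions_ml(f$tree, f$post, threshold = 1.1),
               "parameter error")
})

test_that("raising the threshold never increases the ML event count", {
  withr::local_seed(71)
  for (i in 1:10) {
    tr <- ape::rtree(12)
    lv <- state_levels(2)
    nn <- ape::Ntip(tr) + tr$Nnode
    raw <- matrix(stats::runif(nn * 2), nn, 2)
    post <- raw / rowSums(raw)
    dimnames(post) <- list(nd3shift:::node_names(tr), lv)
    counts <- vapply(c(0.6, 0.7, 0.8, 0.9, 0.99), function(th)
      nrow(count_transitions_ml(tr, post, th)), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("noiseless indicator posteriors give the exact edge census", {
  withr::local_seed(72)
  tr <- ape::rtree(20)
  sim <- simulate_er_states(tr, k = 5L, q = 0.8, seed = 73)
  lv <- state_levels(5)
  truth <- sim$truth$node_states
  post <- matrix(0, length(truth), 5,
                 dimnames = list(names(truth), lv))
  post[cbind(names(truth), truth)] <- 1
  ev <- count_transitions_ml(tr, post, threshold = 1)
  expect_equal(nrow(ev), nrow(sim$truth$events))
  expect_setequal(paste(ev$parent, ev$child),
                  paste(sim$truth$events$parent, sim$truth$events$child))
  ## every event carries exactly one category
  expect_true(all(ev$category %in%
                    c("gain", "loss", "transition", "transversion")))
})

test_that("MP counting requires single-state sets at both ends", {
  tr <- read_newick("((t1:1,t2:1):1,(t3:1,t4:1):1);")
  st <- data.frame(taxon = paste0("t", 1:4), state = c("A", "C", "A", "C"))
  mp <- mp_state_sets(tr, st, k = 5L)
  ## every internal set is \{A, C\}: no edge has two unambiguous ends
  expect_equal(nrow(count_transitions_mp(mp_sets = mp)), 0L)

  st2 <- data.frame(taxon = paste0("t", 1:4),
                    state = c("GAP", "GAP", "C", "C"))
  mp2 <- mp_state_sets(tr, st2, k = 5L)
  ev <- count_transitions_mp(mp_sets = mp2)
  expect_true(all(ev$framework == "MP"))
  expect_true(all(ev$category %in% c("gain", "loss")))
})

test_that("event summaries recount the event list", {
  ev <- data.frame(parent = c("N1", "N1", "N2"), child = c("a", "b", "c"),
                   from = c("GAP", "GAP", "C"), to = c("C", "C", "GAP"),
                   category = c("gain", "gain", "loss"),
                   framework = "ML", stringsAsFactors = FALSE)
  s <- summarize_events(ev)
  expect_equal(unname(s$by_category),
               c(2L, 1L, 0L, 0L))
  expect_equal(s$by_pair$count[s$by_pair$from == "GAP"], 2L)
  expect_equal(sum(s$by_category), nrow(ev))
  s0 <- summarize_events(ev[0, ])
  expect_equal(sum(s0$by_category), 0L)

  ## random recount property
  withr::local_seed(74)
  tr <- ape::rtree(30)
  sim <- simulate_er_states(tr, k = 5L, q = 0.3, seed = 75)
  evs <- sim$truth$events
  evs$category <- mapply(classify_event, evs$from, evs$to)
  evs$framework <- "truth"
  s2 <- summarize_events(evs)
  for (cc in names(s2$by_category))
    expect_equal(unname(s2$by_category[cc]), sum(evs$category == cc))
})
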