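## Generators for trees, discrete-trait histories and ND3-like alignments
## with known truth, so every pipeline stage can be validated end to end
## without any external data.

#' Simulate a pure-birth (Yule) tree
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed RNG seed; the same seed reproduces the tree exactly.
#' @param branch_scale Multiplier applied to all edge lengths (default 1).
#' @param polytomy_tol If > 0, internal edges shorter than this (after
#'   scaling) are collapsed into polytomies, to exercise seeded polytomy
#'   resolution downstream.
#' @return A rooted `phylo` object with tip labels `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, seed, branch_scale = 1,
                               polytomy_tol = 0) {
  if (n_tips < 2L) stop("parameter error: n_tips must be >= 2")
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length * branch_scale
  if (polytomy_tol > 0) tr <- ape::di2multi(tr, tol = polytomy_tol)
  tr
}

#' Simulate a discrete character under the equal-rates Mk model
#'
#' The root state is drawn from the model's root prior (or fixed), then
#' each child state is sampled from the ER transition matrix over its edge
#' length. The full truth — every node state and the exact parent-unequal-
#' child event census — is recorded for later validation; the internal
#' consistency of the two is asserted on every call.
#'
#' @param tree Rooted `phylo` with edge lengths.
#' @param k Number of states (2 or 5).
#' @param q ER substitution rate (>= 0).
#' @param seed RNG seed.
#' @param root_state Optional fixed root state (a `state_levels(k)` label);
#'   default drawn from the uniform prior.
#' @return List with `states` (tip state table), `truth` (list:
#'   `node_states`, `events`, `model` parameters, `seed`).
#' @export
simulate_er_states <- function(tree, k, q, seed, root_state = NULL) {
  k <- as.integer(k)
  lv <- state_levels(k)
  model <- er_model(k, q)
  set.seed(seed)
  n_tip <- ape::Ntip(tree)
  n_tot <- n_tip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  elen <- tr$edge.length
  if (is.null(elen)) elen <- rep(1, nrow(edge))
  node_state <- character(n_tot)
  root <- edge[nrow(edge), 1L]
  node_state[root] <- if (is.null(root_state)) {
    sample(lv, 1L, prob = model$root_prior)
  } else {
    if (!root_state %in% lv) stop("root_state not a valid ", k, "-state label")
    root_state
  }
  ## pre-order down the tree: parents are assigned before their children
  for (i in rev(seq_len(nrow(edge)))) {
    P <- er_transition_matrix(model, elen[i])
    node_state[edge[i, 2L]] <-
      sample(lv, 1L, prob = P[node_state[edge[i, 1L]], ])
  }
  nn <- node_names(tree)
  names(node_state) <- nn
  changed <- node_state[edge[, 1L]] != node_state[edge[, 2L]]
  events <- data.frame(parent = nn[edge[changed, 1L]],
                       child = nn[edge[changed, 2L]],
                       from = unname(node_state[edge[changed, 1L]]),
                       to = unname(node_state[edge[changed, 2L]]),
                       stringsAsFactors = FALSE)
  ## invariant: the recorded event list IS the parent != child census
  census <- sum(node_state[edge[, 1L]] != node_state[edge[, 2L]])
  stopifnot(nrow(events) == census)
  states <- new_state_table(tree$tip.label,
                            unname(node_state[seq_len(n_tip)]), 174L)
  list(states = states,
       truth = list(node_states = node_state, events = events,
                    model = list(k = k, q = q), seed = seed))
}

## fixed synthetic motif around the insertion (columns relative to focal):
## the insertion codon is CT + inserted nucleotide (leucine CTN), the
## shifted frame then reads AGT AGC (two serines) and the corrected +1
## frame reads GTA (valine) and GC+N (alanine). The upstream block is an
## arbitrary but fixed ND3-like context.
MOTIF_UPSTREAM <- c("A", "T", "C", "C", "T", "A", "A", "T", "C")  # focal-11..-3
MOTIF_CORE_DOWN <- c("A", "G", "T", "A", "G", "C")                 # focal+1..+6

#' Simulate an ND3-like codon alignment with a focal +1 insertion
#'
#' Builds an alignment of `L + 1` columns in which the focal column holds
#' the insertion: carriers get their state nucleotide there plus the
#' conserved motif (leucine CTN insertion codon, AGT/AGC in the shifted
#' frame downstream), non-carriers get a gap at the focal column and
#' relaxed conservation downstream of it. Background positions evolve by
#' i.i.d. per-site substitution from a random ancestral sequence. For
#' carriers the shifted reading frame is kept stop-free up to `stop_bp`,
#' where the first in-frame stop codon is planted, so premature-stop
#' scanning has a known truth. Extra frame-breaking indels can be planted
#' for the frameshift scanner; all planted features are recorded in the
#' manifest.
#'
#' @param state_table State table (2- or 5-state) for all taxa; in the
#'   2-state encoding, `present` carriers get a `C` insertion.
#' @param seed RNG seed; the same seed reproduces the alignment exactly.
#' @param L Ungapped gene length without the insertion (default 354).
#' @param focal Focal insertion column (default 174).
#' @param motif_fidelity Per-site probability that a carrier retains the
#'   core motif base (default 0.98); 1 forces complete conservation.
#' @param upstream_fidelity Same for the upstream motif block
#'   (default 0.9).
#' @param background_sub_rate Per-site substitution probability outside
#'   the motif (default 0.05).
#' @param noncarrier_downstream_sub_rate Substitution probability for
#'   non-carriers at the downstream motif columns (default 0.2), emulating
#'   the relaxed conservation seen without the insertion.
#' @param stop_bp Carrier shifted-frame translation ends at this bp
#'   (default 207); `NA` plants no stop and keeps the frame stop-free.
#' @param plant_indels Optional data frame `taxon`, `column`, `kind`
#'   (`insertion`/`deletion`), `length` of extra indels to plant.
#'   Insertions add new columns (shifting downstream coordinates,
#'   including the focal column; consult the manifest).
#' @return List with `alignment` (character matrix) and `manifest` (list:
#'   `focal` after any shifts, `stop_bp`, `planted` with final
#'   coordinates, `seed`).
#' @export
simulate_nd3_alignment <- function(state_table, seed, L = 354L, focal = 174L,
                                   motif_fidelity = 0.98,
                                   upstream_fidelity = 0.9,
                                   background_sub_rate = 0.05,
                                   noncarrier_downstream_sub_rate = 0.2,
                                   stop_bp = 207L, plant_indels = NULL) {
  focal <- as.integer(focal); L <- as.integer(L)
  if (focal - 11L < 1L || focal + 7L > L + 1L)
    stop("parameter error: motif window outside [1, L + 1]")
  set.seed(seed)
  ncol_aln <- L + 1L
  st <- stats::setNames(state_table$state, state_table$taxon)
  carrier <- stats::setNames(!(st %in% c("GAP", "absent")), names(st))
  ins_nuc <- ifelse(st == "present", "C", st)   # 2-state carriers get a C
  ## ancestral background sequence, slightly AT-rich as in mitochondria
  anc <- sample(NUCLEOTIDES, ncol_aln, replace = TRUE,
                prob = c(0.31, 0.24, 0.14, 0.31))
  up_cols <- (focal - 11L):(focal - 3L)
  core_cols <- c(focal - 2L, focal - 1L, (focal + 1L):(focal + 6L))
  core_bases <- c("C", "T", MOTIF_CORE_DOWN)
  anc[up_cols] <- MOTIF_UPSTREAM
  anc[core_cols] <- core_bases
  motif_all <- c(up_cols, core_cols, focal, focal + 7L)
  down_core <- (focal + 1L):(focal + 6L)

  mutate <- function(base) vapply(base, function(b)
    sample(setdiff(NUCLEOTIDES, b), 1L), character(1))

  ## repair shifted-frame premature stops for a carrier row and plant the
  ## terminal stop; never touches the motif columns
  tab <- genetic_code_table(2L)
  fix_stops <- function(row) {
    limit <- if (is.na(stop_bp)) length(row) %/% 3L else (stop_bp %/% 3L) - 1L
    for (i in seq_len(limit)) {
      idx <- (3L * i - 2L):(3L * i)
      if (idx[3L] == focal) next   # the CTN insertion codon is never a stop
      aa <- tab[paste(row[idx], collapse = "")]
      ## TAA/TAG -> TAC (Tyr), AGA/AGG -> AGC (Ser)
      if (!is.na(aa) && aa == "*") row[idx[3L]] <- "C"
    }
    if (!is.na(stop_bp)) row[(stop_bp - 2L):stop_bp] <- c("T", "A", "A")
    row
  }

  taxa <- names(st)
  aln <- matrix("", length(taxa), ncol_aln, dimnames = list(taxa, NULL))
  bg <- setdiff(seq_len(ncol_aln), motif_all)
  for (tx in taxa) {
    row <- anc
    ## third position of the +1-frame alanine codon: all four synonymous
    ## bases occur across taxa
    row[focal + 7L] <- sample(NUCLEOTIDES, 1L)
    hit <- bg[stats::runif(length(bg)) < background_sub_rate]
    if (length(hit)) row[hit] <- mutate(row[hit])
    if (carrier[[tx]]) {
      mut_up <- up_cols[stats::runif(length(up_cols)) > upstream_fidelity]
      mut_core <- core_cols[stats::runif(length(core_cols)) > motif_fidelity]
      if (length(mut_up)) row[mut_up] <- mutate(row[mut_up])
      if (length(mut_core)) row[mut_core] <- mutate(row[mut_core])
      row[focal] <- ins_nuc[[tx]]
      row <- fix_stops(row)
    } else {
      mut_up <- up_cols[stats::runif(length(up_cols)) > upstream_fidelity]
      relax <- down_core[stats::runif(length(down_core)) <
                           noncarrier_downstream_sub_rate]
      if (length(mut_up)) row[mut_up] <- mutate(row[mut_up])
      if (length(relax)) row[relax] <- mutate(row[relax])
      row[focal] <- "-"
    }
    aln[tx, ] <- row
  }

  planted <- data.frame(taxon = character(), column = integer(),
                        kind = character(), length = integer(),
                        stringsAsFactors = FALSE)
  new_focal <- focal
  if (!is.null(plant_indels) && nrow(plant_indels)) {
    pi <- plant_indels[order(plant_indels$column, decreasing = TRUE), ,
                       drop = FALSE]
    for (r in seq_len(nrow(pi))) {
      tx <- pi$taxon[r]; col <- as.integer(pi$column[r])
      len <- as.integer(pi$length[r])
      if (!tx %in% taxa) stop("plant_indels taxon not in state table: ", tx)
      if (pi$kind[r] == "insertion") {
        block <- matrix("-", nrow(aln), len)
        block[match(tx, rownames(aln)), ] <-
          sample(NUCLEOTIDES, len, replace = TRUE)
        aln <- cbind(aln[, seq_len(col - 1L), drop = FALSE], block,
                     aln[, col:ncol(aln), drop = FALSE])
      } else if (pi$kind[r] == "deletion") {
        aln[tx, col:(col + len - 1L)] <- "-"
      } else stop("plant_indels kind must be 'insertion' or 'deletion'")
    }
    ## final coordinates: processed in descending column order, so each
    ## earlier insertion shifts any feature to its right, incl. the focal
    for (r in rev(seq_len(nrow(pi)))) {
      shift <- 0L
      if (pi$kind[r] == "insertion") {
        ins_before <- pi$kind == "insertion" & pi$column < pi$column[r]
        shift <- sum(as.integer(pi$length[ins_before]))
      } else {
        ins_before <- pi$kind == "insertion" & pi$column <= pi$column[r]
        shift <- sum(as.integer(pi$length[ins_before]))
      }
      planted[nrow(planted) + 1L, ] <-
        list(pi$taxon[r], as.integer(pi$column[r]) + shift,
             pi$kind[r], as.integer(pi$length[r]))
    }
    ins_before_focal <- pi$kind == "insertion" & pi$column <= focal
    new_focal <- focal + sum(as.integer(pi$length[ins_before_focal]))
    planted <- planted[order(planted$column, planted$taxon), , drop = FALSE]
    rownames(planted) <- NULL
  }
  colnames(aln) <- NULL
  list(alignment = aln,
       manifest = list(focal = new_focal, stop_bp = stop_bp,
                       planted = planted, seed = seed,
                       motif_fidelity = motif_fidelity))
}
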