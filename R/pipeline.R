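## One-call orchestration of the full analysis: state calling -> ancestral
## reconstruction (2- and 5-state ML, 2-state MP) -> transition counting ->
## conservation profiling -> dual-frame codon tables -> frameshift scan,
## with all tables written to disk plus a machine-readable report.json.

#' Read a flat key = value run configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values may be
#' quoted strings, numbers, or `true`/`false`. Section headers in square
#' brackets are ignored (keys are flat).
#'
#' @param path Path to the config file.
#' @return Named list of values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln)) stop("config error: malformed line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- if (val %in% c("true", "false")) {
      val == "true"
    } else if (grepl("^-?[0-9.eE+]+$", val) &&
               !is.na(suppressWarnings(as.numeric(val)))) {
      as.numeric(val)
    } else val
  }
  out
}

## internal: posterior / set tables for writing
posterior_df <- function(post) {
  data.frame(node = rownames(post), as.data.frame(unname(post)) |>
               stats::setNames(colnames(post)),
             check.names = FALSE, stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full insertion analysis
#'
#' Executes every stage of the analysis on a supplied alignment + tree or
#' on a freshly simulated dataset, writes all per-stage tables under
#' `out_dir`, and returns (and writes as `report.json`) a machine-readable
#' report. Re-running with the same configuration and seed reproduces the
#' report bit-identically (no timestamps in the report body).
#'
#' @param config Named list or path to a flat config file
#'   ([read_run_config()]). Recognised keys: `alignment`, `tree` (paths) or
#'   `simulate = TRUE` with `sim_n_tips`, `sim_k`, `sim_q`; `focal`
#'   (default 174), `min_col_frac` (0.05), `threshold` (0.90), `seed` (1),
#'   `window_start`/`window_end` (163/180), `min_support_frac` (0.8),
#'   `clades` (path to a TSV `taxon<TAB>clade` for MRCA posteriors),
#'   `out_dir` (required).
#' @return The report, a nested list (also written to
#'   `out_dir/report.json`).
#' @export
run_full_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  cfg <- function(key, default = NULL) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  out_dir <- cfg("out_dir")
  if (is.null(out_dir)) stop("config error: 'out_dir' is required")
  focal <- as.integer(cfg("focal", 174L))
  seed <- as.integer(cfg("seed", 1L))
  threshold <- cfg("threshold", 0.90)
  min_col_frac <- cfg("min_col_frac", 0.05)
  window <- c(as.integer(cfg("window_start", 163L)),
              as.integer(cfg("window_end", 180L)))

  simulate <- isTRUE(cfg("simulate", FALSE))
  if (!simulate && (is.null(cfg("alignment")) || is.null(cfg("tree"))))
    stop("config error: need 'alignment' and 'tree' paths, or ",
         "'simulate = true'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  message("[nd3shift] seed = ", seed, ", focal = ", focal)
  truth <- NULL
  if (simulate) {
    n_tips <- as.integer(cfg("sim_n_tips", 128L))
    k_sim <- as.integer(cfg("sim_k", 5L))
    q_sim <- cfg("sim_q", 0.05)
    message("[nd3shift] simulating: ", n_tips, " tips, k = ", k_sim,
            ", q = ", q_sim)
    tree <- simulate_yule_tree(n_tips, seed = seed)
    tree$edge.length <- rep(1, nrow(tree$edge))
    sim <- simulate_er_states(tree, k = k_sim, q = q_sim, seed = seed + 1L)
    nd3 <- simulate_nd3_alignment(sim$states, seed = seed + 2L,
                                  focal = focal)
    aln <- nd3$alignment
    focal <- nd3$manifest$focal
    truth <- sim$truth
    write_fasta_alignment(aln, file.path(out_dir, "aln.fasta"))
    write_newick(tree, file.path(out_dir, "tree.nwk"))
  } else {
    aln <- read_fasta_alignment(cfg("alignment"))
    tree <- read_newick(cfg("tree"))
  }

  ## --- state calling -------------------------------------------------
  fc <- filter_columns(aln, min_col_frac)
  focal2 <- fc$column_map[focal]
  if (is.na(focal2))
    stop("focal column ", focal, " was removed by the occupancy filter")
  qc <- qc_filter_taxa(fc$alignment, focal2)
  states <- call_states(qc$kept, focal2, qc = FALSE)
  write_state_table(states, file.path(out_dir, "states.tsv"))
  write_tsv(qc$dropped, file.path(out_dir, "dropped_taxa.tsv"))

  rec <- reconcile(states, tree)
  states <- rec$data; tree_m <- rec$tree
  tree_m$edge.length <- rep(1, nrow(tree_m$edge))  # equal-lengths analysis
  message("[nd3shift] ", nrow(states), " taxa after QC/reconciliation")

  ## --- ancestral state reconstruction --------------------------------
  fit2 <- fit_rate(tree_m, states, k = 2L)
  post2 <- marginal_posteriors(tree_m, states, fit2)
  fit5 <- fit_rate(tree_m, states, k = 5L)
  post5 <- marginal_posteriors(tree_m, states, fit5)
  mp2 <- mp_state_sets(tree_m, states, k = 2L, seed = seed)
  write_tsv(posterior_df(post2), file.path(out_dir, "posteriors_2state.tsv"))
  write_tsv(posterior_df(post5), file.path(out_dir, "posteriors_5state.tsv"))
  write_tsv(data.frame(node = names(mp2$sets),
                       states = vapply(mp2$sets, paste, "", collapse = ",")),
            file.path(out_dir, "mp_state_sets.tsv"))

  ## --- transition events ---------------------------------------------
  ev_ml2 <- count_transitions_ml(tree_m, post2, threshold)
  ev_ml5 <- count_transitions_ml(tree_m, post5, threshold)
  ev_mp2 <- count_transitions_mp(mp_sets = mp2)
  write_tsv(ev_ml2, file.path(out_dir, "events_ml_2state.tsv"))
  write_tsv(ev_ml5, file.path(out_dir, "events_ml_5state.tsv"))
  write_tsv(ev_mp2, file.path(out_dir, "events_mp_2state.tsv"))

  ## --- MRCA posteriors for named clades ------------------------------
  clade_post <- NULL
  if (!is.null(cfg("clades"))) {
    cl <- utils::read.delim(cfg("clades"), stringsAsFactors = FALSE)
    clade_post <- lapply(split(cl$taxon, cl$clade), function(tx) {
      tx <- intersect(tx, tree_m$tip.label)
      if (length(tx) < 2L) return(NULL)
      node <- ape::getMRCA(tree_m, tx)
      nm <- node_names(tree_m)[node]
      list(node = nm, posterior_2state = as.list(post2[nm, ]),
           posterior_5state = as.list(post5[nm, ]))
    })
  }

  ## --- conservation profiles -----------------------------------------
  carriers <- states$taxon[states$state != "GAP" & states$state != "absent"]
  noncarriers <- setdiff(states$taxon, carriers)
  if (length(carriers) == 0L || length(noncarriers) == 0L)
    message("[nd3shift] one of the groups is empty; window comparison skipped")
  prof_with <- conservation_profile(qc$kept, intersect(carriers, rownames(qc$kept)),
                                    "with insertion")
  prof_without <- conservation_profile(qc$kept,
                                       intersect(noncarriers, rownames(qc$kept)),
                                       "without insertion")
  write_tsv(prof_with, file.path(out_dir, "conservation_with.tsv"))
  write_tsv(prof_without, file.path(out_dir, "conservation_without.tsv"))
  win_cmp <- if (length(carriers) && length(noncarriers))
    compare_windows(prof_with, prof_without, window) else NULL
  logo_win <- c(window[1L], window[2L] + 1L)
  logo <- logo_matrix(prof_with, logo_win)
  write_tsv(data.frame(position = rownames(logo), logo),
            file.path(out_dir, "logo_with.tsv"))

  ## --- codon usage -----------------------------------------------------
  cod <- rbind(codon_frequencies(qc$kept, intersect(carriers, rownames(qc$kept)),
                                 frame = 0L, focal = focal2),
               codon_frequencies(qc$kept, intersect(carriers, rownames(qc$kept)),
                                 frame = 1L, focal = focal2))
  write_tsv(cod, file.path(out_dir, "codons.tsv"))

  ## --- frameshift scan -------------------------------------------------
  fs <- scan_frameshifts(qc$kept,
                         min_support_frac = cfg("min_support_frac", 0.8),
                         exclude_column = focal2)
  write_tsv(fs, file.path(out_dir, "frameshift_candidates.tsv"))

  ## --- report ----------------------------------------------------------
  top_codon <- function(df, fr, slot) {
    d <- df[df$frame == fr & df$slot == slot, ]
    if (!nrow(d)) return(NULL)
    list(codon = d$codon[1L], freq = d$freq[1L], aa = d$aa[1L])
  }
  report <- list(
    parameters = list(seed = seed, focal = focal, threshold = threshold,
                      min_col_frac = min_col_frac, window = window,
                      simulate = simulate),
    states = list(n_taxa = nrow(states),
                  counts = as.list(table(states$state)),
                  n_dropped_qc = nrow(qc$dropped)),
    asr = list(q_2state = fit2$q, loglik_2state = fit2$loglik,
               q_5state = fit5$q, loglik_5state = fit5$loglik,
               mp_score = mp2$score,
               clade_posteriors = clade_post),
    events = list(ml_2state = as.list(summarize_events(ev_ml2)$by_category),
                  ml_5state = as.list(summarize_events(ev_ml5)$by_category),
                  mp_2state = as.list(summarize_events(ev_mp2)$by_category)),
    conservation = win_cmp,
    codons = list(
      insertion_codon = top_codon(cod, "0", "insertion codon"),
      frame0_following1 = top_codon(cod, "0", "following codon 1"),
      frame0_following2 = top_codon(cod, "0", "following codon 2"),
      frame1_following1 = top_codon(cod, "+1", "following codon 1"),
      frame1_following2 = top_codon(cod, "+1", "following codon 2")),
    frameshift_scan = list(n_candidates = nrow(fs),
                           candidates = fs))
  if (!is.null(truth))
    report$simulation_truth <- list(n_true_events = nrow(truth$events),
                                    q_true = truth$model$q,
                                    k_true = truth$model$k)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("[nd3shift] report written to ", file.path(out_dir, "report.json"))
  invisible(report)
}
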