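---
title: "Models and methods behind nd3shift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nd3shift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nd3shift)
```

`nd3shift` analyses a single-nucleotide (+1) frameshift insertion in a
protein-coding mitochondrial gene — the motivating case is position 174 of
ND3 in birds and turtles — as a discrete character on a phylogeny, together
with the sequence context that appears to make the insertion tolerable.
This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## The character and its calling

The character is the content of one alignment column: a gap means the
insertion is absent, a nucleotide means it is present as that base. Two
encodings are used throughout: 2-state (`absent`/`present`) and 5-state
(`GAP`, `A`, `C`, `G`, `T`). State calling applies two quality filters
first:

* **Column occupancy** (`filter_columns`, default `min_frac = 0.05`):
  columns with residues in fewer than 5% of records are removed, so that
  rare private insertions do not inflate the coordinate system. The
  boundary is inclusive (exactly 5% is kept), and `N` counts as a residue
  observation, not a gap. A column map is returned so the focal coordinate
  can be re-located after filtering; all interfaces speak 1-based alignment
  columns.
* **Flank QC** (`qc_filter_taxa`): any record with a gap or `N` in the two
  codons (six columns) on either side of the focal column is dropped — the
  insertion call is only as good as its local alignment. The focal column
  itself is *not* examined, because a gap there is the legitimate
  "absent" state. An `N` exactly at the focal column drops the record:
  presence versus absence cannot be decided, and a conservative drop beats
  an arbitrary call. The window is measured in alignment columns (gaps
  included), matching filtering on the alignment itself.

## Equal-rates Mk ancestral reconstruction

The evolutionary model is the equal-rates (ER) Mk model: a continuous-time
Markov chain on k states with a single rate `q` for every ordered state
pair (rate matrix off-diagonals `q`, diagonals `-(k-1)q`). It is the
least-committal choice when nothing is known about the relative
probabilities of gain, loss and substitution. Its transition probabilities
have the closed form

P_ii(t) = 1/k + (k−1)/k · e^(−kqt),  P_ij(t) = 1/k − 1/k · e^(−kqt),

which the package uses directly instead of a numerical matrix exponential
(the two agree to 1e−10 in the test suite).

* **Likelihood** (`prune_loglik`): Felsenstein pruning over the rooted
  tree, polytomies handled natively, with per-node rescaling by the
  maximum partial likelihood to prevent underflow. The root conditionals
  are combined with the root prior.
* **Root prior**: uniform (`1/k`) by default — it is the ER stationary
  distribution, and nothing in the data motivates anything else.
  It can be replaced via `er_model()`.
* **Rate fit** (`fit_rate`): 1-D bounded maximisation by `stats::optimize`
  over `q ∈ [1e-8, q_max]`, tolerance 1e−8. `q_max` defaults to
  `100 / (mean root-to-tip path length)` — beyond that the process is
  effectively saturated and the likelihood surface flat. Monomorphic tip
  data contain no change signal, so the rate is pinned at the lower bound
  with a warning rather than letting the optimiser wander a flat surface.
* **Marginal posteriors** (`marginal_posteriors`): the rerooting method —
  the marginal posterior of a node is the root posterior of the tree
  rerooted at that node. Because the ER model is time-reversible with a
  uniform stationary distribution, this is computed exactly by one
  post-order pass (conditional likelihoods below each node) plus one
  pre-order pass (likelihood of the rest of the tree), without literal
  rerooting; the test suite checks equality against literal rerooting to
  1e−10 and against brute-force enumeration to 1e−9. Tips with observed
  states get indicator posteriors. Missing tip states are treated as fully
  ambiguous (all-ones partial) with a warning, or rejected via
  `missing = "error"`; the default pipeline assumes complete data because
  the QC filter removes undecidable records.
* **Branch lengths**: the pipeline sets every edge length to 1 before
  reconstruction — the appropriate convention for synthesis trees that
  carry no branch lengths — and `read_newick` fills unit lengths when a
  tree has none at all (a tree with only some lengths is rejected as
  malformed). Functions accept real lengths if the caller keeps them.

**Maximum parsimony** (`mp_state_sets`) is the non-parametric
counterpart: Sankoff dynamic programming with unit cost. Polytomies are
resolved to an arbitrary binary tree first (seeded, so reproducible; the
MP score on an already-binary tree does not depend on the seed). An
up-pass computes minimal subtree costs, a down-pass the minimal cost of
the remainder, and a state belongs to a node's set iff subtree + remainder
costs sum to the global minimum — i.e. the set of states attained in at
least one most-parsimonious reconstruction. Directionality of events is
read off the rooted input tree.

## Event counting

`count_transitions_ml` applies a deliberately conservative evidence rule:
a node is called only when its maximum posterior reaches the threshold
(default 0.90), and an event is emitted only when *both* ends of an edge
are called and differ. The threshold must lie in (0.5, 1], which makes the
thresholded argmax unique; raising it can only remove events (tested as a
monotonicity property). With noiseless indicator posteriors and threshold
1, counting reduces to the exact parent≠child edge census. Edges incident
to the root are treated like any other. `count_transitions_mp` emits an
event only when both ends have single-state MP sets. Events are classified
gain (gap→nucleotide), loss (nucleotide→gap), transition (purine↔purine or
pyrimidine↔pyrimidine) or transversion (purine↔pyrimidine); the 2-state
encoding can only produce gains and losses.

## Conservation and codon usage

Per-column nucleotide frequencies exclude gaps and `N` from numerator and
denominator — a gap-dominated column must not masquerade as conserved — and
report coverage separately; a zero-coverage column has *undefined* (not
zero) entropy. Shannon entropy `H = −Σ f log2 f` (with `0·log2 0 = 0`) and
information content `R = 2 − H` give the usual 0–2 bit conservation scale,
and logo heights are `f·R`.

The carrier/non-carrier contrast (`compare_windows`) is a two-sided
Wilcoxon rank-sum test on the per-position R values of the two groups in a
window (default 163–180; the logo window default is 163–181 — the two
defaults intentionally differ because the statistics window and the
display window serve different purposes). The summary statistic is
`(mean R_with − mean R_without) / mean R_with × 100`, i.e. how much lower
the non-carrier group is as a percentage of the carrier mean; the choice
of mean and denominator is stated in the output metadata. Positions with
undefined R in a group (e.g. the focal column in the non-carrier group,
which is all gaps there) are excluded from both the test and the means.
When every value is tied across both groups the normal-approximation
p-value is undefined and is reported as 1.

Codon tables are computed in two frames. Frame 0 reads straight through
the insertion: slots at columns `focal−2..focal` (the insertion codon),
`focal+1..focal+3`, `focal+4..focal+6`. Frame +1 is the corrected frame,
skipping the single nucleotide immediately after the insertion: slots
`focal−2..focal`, `focal+2..focal+4`, `focal+5..focal+7`. The insertion
codon slot is identical in both frames by construction. Codons containing
`N` are removed before normalisation, and a slot containing a gap is
skipped for that row. Translation uses NCBI table 2 (vertebrate
mitochondrial: AGA/AGG stop, ATA Met, TGA Trp; switchable via `numcode`),
and amino acids are annotated with a standard four-class scheme
(nonpolar A V L I P F W M G; polar S T C Y N Q; basic K R H; acidic D E).
`premature_stop_scan` translates an ungapped sequence from position 1 and
returns the end position of the first stop codon — for a carrier read in
the shifted frame this is the premature termination point of the
uncorrected product.

## Frameshift scanning

`scan_frameshifts` re-derives frameshift candidates from gap patterns
alone, so the module needs no external aligner annotations (an importer
for `!`-marked FASTA from codon-aware aligners is provided as a
convenience). The alignment consensus defines the frame: a column where at
least `min_support_frac` (default 0.8) of sequences have gaps is an
insertion column, one where at least that fraction have residues is a
frame column. Per sequence, maximal runs of residues in insertion columns
(insertions) and of gaps in frame columns (deletions) whose length is not
a multiple of 3 are reported with their net frame offset (1 or 2); a run
of length 2 is reported once with offset 2, which covers
"either-of-two-adjacent-columns" deletion ambiguity. Runs covering a
supplied focal column can be excluded to find *other* frameshifts.
Columns with intermediate gap fractions support neither call — a stated
operationalisation of what is otherwise a visual-inspection judgement.
Adjacent insertion and deletion runs are reported separately.

## The synthetic-data generator

The generator exists so that every stage can be validated against known
truth. `simulate_yule_tree` draws a pure-birth tree;
`simulate_er_states` evolves the character under the exact ER transition
matrices, recording every node state and the full event census (asserted
internally on every call); `simulate_nd3_alignment` builds an ND3-like
alignment of `L + 1 = 355` columns in which the focal column carries the
insertion.

Defaults and what they emulate:

* Carriers receive the conserved motif: `CT` at `focal−2, focal−1` (so the
  insertion codon is leucine `CTN`), `AGTAGC` at `focal+1..focal+6` (the
  two shifted-frame serine codons; in the corrected frame these read
  `GTA` valine followed by `GC·N` alanine). Per-site motif fidelity is
  0.98 (fidelity 1 forces `R = 2` downstream of the insertion in the
  carrier group). The third position of the alanine codon varies freely
  across taxa, as all four synonymous codons occur in real carriers.
* Non-carriers get a gap at the focal column and a relaxed downstream
  motif (substitution probability 0.2 at `focal+1..focal+6`), emulating
  the weaker conservation observed without the insertion.
* The upstream block (`focal−11..focal−3`) is a fixed synthetic context
  applied with fidelity 0.9 to both groups — moderate conservation with
  third-position wobble.
* Background columns evolve i.i.d. from a random, slightly AT-rich
  ancestral sequence with per-site substitution probability 0.05. These
  are star-phylogeny substitutions, chosen for simplicity: background
  columns carry no phylogenetic signal, which is irrelevant to the
  analyses (only the focal character is reconstructed) but means the
  generator does *not* emulate realistic among-site rate variation,
  codon-model selection, or indel evolution along the tree.
* The carrier shifted reading frame is kept stop-free up to `stop_bp`
  (default 207, i.e. early termination at 207 bp versus the full 354 bp)
  where a `TAA` is planted, so the premature-stop scan has an exact truth.
  Repairs never touch the focal column.
* Extra single- or multi-nucleotide indels can be planted for the
  frameshift scanner; planted insertions add columns and therefore shift
  downstream coordinates, including the focal column — the manifest
  records the final coordinates and focal position.
* 2-state `present` carriers are given a `C` insertion, the dominant
  nucleotide in the real data.

Passing tests on this generator demonstrate algorithmic correctness —
exact state recovery, indel recovery, calibrated posteriors under the
generating model — not robustness to real-data pathologies (alignment
error, saturation, model misspecification, rate variation), which the
generator deliberately does not contain.

## Problem sizes and numerical choices

The validation battery uses exhaustive enumeration oracles on trees of up
to 8 tips (likelihood, parsimony) and 6 tips (marginals, 5-state), 100
random trees per criterion; rate recovery uses 50 replicates of 256-tip
Yule trees at `q = 0.1` (median within [0.07, 0.13]); the end-to-end
check uses three 256-tip replicates at `q = 0.05` pooled for the ≥95%
high-confidence-node accuracy bound. These sizes make the whole suite run
in well under a minute while keeping the enumeration spaces (2^7 to 5^7
assignments) non-trivial.

Numerical conventions: per-node rescaling in both passes; posterior rows
renormalised and checked to sum to 1 within 1e−9; `0·log2 0 := 0`;
optimisation tolerance 1e−8; ties at the thresholded argmax are impossible
by the threshold precondition (> 0.5). Degenerate inputs are errors, not
silent defaults: empty alignments, out-of-bounds windows, negative branch
lengths, partially-specified edge lengths, missing MP tip states.

## Known limitations

* Only the equal-rates Mk model is implemented — no all-rates-different
  variants, rate heterogeneity, joint (as opposed to marginal)
  reconstruction, or branch-length estimation.
* The rerooting-equivalence of the two-pass marginal algorithm relies on
  reversibility; with a non-uniform root prior the output is the standard
  marginal posterior but no longer identical to naive rerooting.
* The frameshift scanner assumes a codon-aware alignment whose consensus
  defines the frame; it does not align sequences itself and has no notion
  of sequencing error.
* Identifier reconciliation takes the intersection of taxa and prunes the
  tree (suppressing degree-2 nodes, summing lengths); how a published
  synthesis tree was rooted or matched is outside the package's control
  and should be checked by the user.
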