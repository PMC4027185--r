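---
title: "Models and design choices in splicescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in splicescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescreen)
```

`splicescreen` screens paralogous exon families for loci where splicing
requirements plausibly constrain protein evolution: a weak splice site in
one member, compensated by exonic splicing enhancers (ESEs) that are absent
— along with the residues their codons encode — from a strong-splice-site
relative. This vignette explains the underlying models, the parameters that
matter, what the simulators do and do not emulate, and the numerical
choices made where the design was open.

## Motif scanning

Two motif representations are supported, matching how ESE/ESS resources are
published.

**Position weight matrices.** A PWM is a width × 4 table of additive
scores; a window scores the sum of its per-position entries, and
`scan_pwm()` reports windows at or above a cutoff. Published SR-protein
matrices come with heterogeneous conventions for their "90% threshold", so
both interpretations are supported: the default resolves a fraction *f*
against the matrix score range,

\[ \mathrm{cutoff} = s_{\min} + f\,(s_{\max} - s_{\min}), \qquad
   s_{\max} = \sum_i \max_b M_{ib},\; s_{\min} = \sum_i \min_b M_{ib}, \]

with `threshold_type = "absolute"` available for users holding published
per-matrix cutoffs. A percentile of a background score distribution would
be a third reading; it is not implemented because it requires a background
corpus the tool should not silently invent.

Scanning is on the given (sense) strand only — pre-mRNA splicing signals
are strand-specific — and windows containing non-ACGT characters are
skipped by the scanner while `pwm_score()` on an explicit window is strict
and errors. Coordinates are 0-based half-open internally and in BED output,
1-based inclusive in report TSVs.

**Hexamer sets.** Enhancer sets are scanned by presence/absence, every
overlapping occurrence reported. Silencer sets carry per-member scores,
`log2(f_{\mathrm{pseudoexon}} / f_{\mathrm{exon}})` (`ess_logodds()`); all
log-odds in the package are base 2 (bits).

## The maximum-entropy splice-site model

Splice-site strength is scored over fixed windows straddling the boundary:
donor 9-mers (3 exonic + 6 intronic) and acceptor 23-mers (20 intronic + 3
exonic), the standard windows of the maximum-entropy splice-site
literature; both are configurable through `site_window_spec()`.

`train_maxent()` estimates the signal distribution as the maximum-entropy
distribution over 4^width windows whose marginals on a chosen set of
position subsets equal the (pseudocounted) empirical marginals of the
training windows:

* **singletons** — the solution is the product of per-position base
  frequencies, i.e. the classical weight matrix;
* **singletons + adjacent pairs** (the default, `"chain"`) — the solution
  factorises exactly as a first-order chain,
  \( P(x) = P(x_1)\prod_i P(x_{i+1} \mid x_i) \), so acceptor-width models
  never materialise a 4^23 table and normalisation is exact;
* **arbitrary subsets** — fitted on the full table by iterative
  proportional fitting (IPF), limited to width ≤ 9 where the table (4^9)
  is still small.

A site scores `log2(P_signal(w) / P_background(w))` bits. The background
defaults to uniform over bases, which keeps the tool self-contained; a
decoy corpus can be supplied instead. Weak/strong classification uses two
cutoffs, `c(weak_below = 3, strong_at_or_above = 6)` bits by default; the
screen takes them as explicit parameters so no strength threshold is
hidden.

**Pseudocounts and constraint consistency.** Zeros are removed by adding a
pseudocount (default 0.5 per contingency cell) — but naively pseudocounting
each constraint table separately makes constraints of different sizes
mutually inconsistent, and IPF then has no fixed point. All targets are
therefore computed as marginals of a *single* smoothed joint: the empirical
counts plus a uniform pseudo-mass of `0.5 × 4^(largest subset size)`. With
that convention the singleton and chain closed forms are exact special
cases of the IPF solution, which the tests verify directly.

**Numerical behaviour.** IPF runs until the largest marginal discrepancy
falls below `tol` (default 1e-8) or `max_iter` sweeps (default 200); a
non-converged fit is returned with `converged = FALSE` and a warning, never
silently. The closed forms report zero iterations and zero discrepancy.
Degenerate inputs behave sensibly: identical training windows yield a
distribution concentrating (up to pseudocount) on that window, and an
empty training set errors. Model files serialise every probability at 17
significant digits, so write → read → write is byte-identical and scores
are bit-for-bit reproducible.

## Codon-aware alignment

Families are compared on the protein level first — the screened families
are paralogs aligned over a shared domain — so `align_pair()` translates
the complete codons of each exon (leading/trailing partial codons at
phase-shifted exon boundaries are excluded from translation but tracked in
coordinates), aligns globally with affine gaps (BLOSUM62, gap open 10,
extend 0.5, via `Biostrings::pairwiseAlignment`), and back-threads
nucleotides codon-per-residue, so gaps are always whole codons. An
exhaustive-recursion dynamic-programming oracle in the test suite confirms
the scores on all short inputs.

`align_family()` aligns additional members progressively against the first
record as anchor and merges anchor gap patterns by taking the longest
insertion per anchor slot. This is adequate for the ≥ 90%-identical
families the screen targets and is documented as such — it is not a general
multiple aligner.

## The candidate screen

`screen_pair()` evaluates both orientations of a pair and emits a candidate
when all of the following hold at the site of interest:

1. the putative weak member classifies *weak* and the other *strong*, with
   contrast `≥ min_delta` bits (`min_delta` is deliberately a required
   screening parameter: no default contrast is scientifically neutral);
2. the weak member has ESE hits whose projected alignment columns carry
   **no same-set hit** in the strong member — absence is judged per motif
   set, not per exact hexamer, because a different enhancer of the same
   family at the same columns still provides the function;
3. a nonsynonymous difference lies within `adjacency_window` codons of the
   hit span (default 1: a residue immediately adjacent to a predicted ESE
   can be functionally part of it even when the prediction misses it).

Silencer hits overlapping retained spans are reported as context only; no
silencer criterion is enforced. Structure-aware filtering (restricting to
an active site) is supported only as an explicit user-supplied column mask.
Both acceptor and donor sites are screened by default; the motivating
biological case is the acceptor.

## Ancestral and orthologous scans

`trim_to_exon()` restricts a multi-species alignment (leaves plus
reconstructed internal-node rows; reconstruction itself is consumed, not
performed) to the reference exon ± `flank` nt (default 30), mapping the
interval through the reference row's gaps; flanks running past the
reference are truncated with a `short_flank` flag rather than an error, and
trimming is idempotent. `scan_nodes()` projects the exon boundaries from
the reference through alignment columns onto every node — nodes with gaps
inside a site window get `gap_in_site_window` and a missing score instead
of a guessed boundary — then scans each node's degapped exon body for
motifs and scores both sites. `annotate_tree()` writes scores as `[&...]`
comment blocks after newick labels, with a companion parser for round
trips.

## Kinetics

`fit_mm()` fits `v = Vmax·S/(Km + S)` by nonlinear least squares
(Levenberg–Marquardt), initialised at `Vmax₀ = max(v)` and `Km₀ = S`
nearest the half-maximal observation, with two seed-jittered restarts on
failure. Standard errors come from the Jacobian. Units are fixed
throughout: S and Km in mM, v and Vmax in µM·s⁻¹, so catalytic efficiency
is `kcat / (Km × 1000)` in s⁻¹·µM⁻¹. `kcat` is either supplied (published
tables print it) or derived as `Vmax/[E]` from an enzyme molar
concentration; no hidden mass-to-molar conversion is attempted. Enzymes
with activity below assay background are represented by
`undetectable_fit()` — a distinct state, never zeros. Group comparisons use
the equal-variance two-sample t-test on replicate fits, matching how such
measurements are conventionally analysed; velocity tables accept comma
decimal separators on input.

## What the simulators emulate — and what they do not

`sim_paralog_family()` builds the screened scenario with a known truth
ledger: near-identical exons (background divergence is strictly synonymous,
so engineered ablations are the only amino-acid differences), an in-frame
enhancer hexamer planted at a stated codon in stated members, and site
windows sampled from the supplied trained models until the requested
weak/strong classification is realised — strength is defined in-model, not
by magic strings. The exon's final codon is pinned to a donor-compatible
codon so a strong donor site is always reachable regardless of the random
exon. Spurious occurrences of planted hexamers are scrubbed synonymously
everywhere, so hit expectations are exact.

Ablation of the planted motif in non-carrier members is **nonsynonymous by
default**: the scenario under study is precisely an enhancer whose loss
coincides with an amino-acid difference, and a synonymous ablation produces
(by design, and verifiably) no candidate. The synonymous mode is available
to emulate the converse case where code degeneracy preserves the residue
while the screen stays silent.

Defaults follow the motivating study's scales: 40-codon exons, 97%
nucleotide identity (the tissue-specific paralogs are 90–98% homologous),
30-nt flanks (exon ± 30 bp is the scanned unit in the comparative
analysis), acceptor weakness as the planted contrast. The generators are
pure functions of their arguments and seed (bitwise-reproducible).

What they do **not** emulate: realistic phylogenetic divergence (no indel
process, no rate heterogeneity, no tree-shaped correlation between
members), codon-usage bias, GC heterogeneity, real SR-protein binding
preferences, or genomic background motif density. Passing tests therefore
demonstrate that the algorithms implement their definitions and recover
planted signals under controlled conditions — not that the screen's
sensitivity/specificity on real genomes matches the simulated one.

The packaged motif files under `inst/extdata/` are synthetic stand-ins
emulating the *formats and set sizes* of the published resources (four
SR matrices of widths 7, 8, 7, 6; 238 enhancer hexamers; 103 scored
silencer hexamers). Analyses of real sequence must substitute the published
files, which the readers accept unchanged.

## Problem sizes used by the checks

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which the statistical checks are stable: splice
models trained on 1500–2000 sampled windows; chain-marginal recovery on
5000 windows; exhaustive model/oracle comparisons at widths 4–6; 100
alignment-oracle pairs of ≤ 8 residues; 50 planted and 50 null families for
screen recovery; Michaelis–Menten refits on 12 log-spaced concentrations
spanning 0.01–20 mM with 6 replicates at 1% noise.

## Known limitations

* The maximum-entropy model supports arbitrary constraint subsets only up
  to width 9; wider windows require singleton or chain constraints (the
  default). Higher-order constraint graphs that remain tractable at width
  23 (e.g. arbitrary trees via junction-tree normalisation) are not
  implemented.
* `align_family()` is anchor-progressive, not a true multiple aligner.
* The screen treats motif sets as the unit of enhancer function; partial
  overlaps between a hit and the strong member's same-set hit count as
  presence, which is conservative.
* No numeric splice-site scores are published for the motivating family's
  exons, so strength classification is validated on synthetic sites, not
  against published per-exon values.
* Weak/strong cutoffs (3/6 bits) and `min_delta` are screening knobs, not
  estimated quantities; sensible values depend on the training corpus and
  should be chosen by inspecting score distributions of known sites.
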