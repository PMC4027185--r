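# splicescreen

Coding exons carry more than protein information: exonic splicing enhancers
(ESEs) — short motifs typically bound by SR proteins — are required for the
spliceosome to recognise exons with weak splice sites. Because ESEs overlap
codons, an amino-acid substitution that would improve a protein can
simultaneously destroy an enhancer and wreck splicing of the exon, so the
"better" protein variant is never produced. `splicescreen` is an R toolkit
for finding and characterising such loci in paralogous gene families — the
scenario exemplified by the human alkaline phosphatase family, where the
tissue-specific paralogs carry a weak 3′ splice site compensated by ESEs
that are absent (together with the corresponding residues) from the
strong-splice-site tissue-non-specific paralog.

It is aimed at molecular evolution and RNA-splicing researchers who have a
set of paralogous (or orthologous/ancestral) exon sequences and want to ask:
*which amino-acid differences between family members are plausibly
constrained by splicing rather than by protein function?*

## What it computes

* **Motif scanning** (`scan_pwm()`, `scan_hexamers()`, `scan_motifs()`):
  position-weight-matrix scans of SR-protein motifs with a
  fraction-of-score-range threshold (default 90%), presence/absence scans of
  enhancer hexamer sets, and silencer hexamer sets scored by
  `log2(f_pseudoexon / f_exon)`.
* **Splice-site strength** (`train_maxent()`, `score_site()`,
  `classify_strength()`): a trainable maximum-entropy model over fixed
  windows — donor 9-mers (3 exonic + 6 intronic) and acceptor 23-mers
  (20 intronic + 3 exonic). Given empirical marginals on chosen position
  subsets, the fitted signal distribution is the maximum-entropy
  distribution matching them, and a site scores
  `log2(P_signal(w) / P_background(w))` bits. Singleton constraints recover
  the classical weight matrix; singleton + adjacent-pair constraints give an
  exact first-order chain; arbitrary subsets are fitted by iterative
  proportional fitting.
* **Codon-aware alignment** (`align_pair()`, `align_family()`,
  `diff_columns()`): translate, align proteins globally (BLOSUM62, affine
  gaps), back-thread nucleotides codon-per-residue, and query columns for
  synonymous/nonsynonymous differences.
* **The candidate screen** (`screen_family()`): flags a pair when (i) one
  member's site is weak and the other's strong with at least `min_delta`
  bits of contrast, (ii) the weak member carries ESE hits whose aligned
  columns carry no same-set hit in the strong member, and (iii) a
  nonsynonymous difference lies within `adjacency_window` codons of the ESE
  span. Silencer hits are attached as context.
* **Ancestral/orthologous scans** (`trim_to_exon()`, `scan_nodes()`,
  `annotate_tree()`): trim a multi-species alignment with reconstructed
  internal-node sequences to an exon ± flanks, profile every node for
  motifs and site strengths, and write an annotated newick.
* **Enzyme kinetics** (`fit_mm()`, `derive_efficiency()`,
  `compare_fits()`): Michaelis–Menten nonlinear least squares
  (`v = Vmax·S/(Km+S)`), turnover and catalytic efficiency
  (`kcat/Km`, with the mM→µM conversion), and equal-variance t-tests
  between enzymes.
* **Simulators** (`sim_paralog_family()`, `sim_splice_windows()`,
  `sim_mm_data()`): generate every input above with a known truth ledger,
  so the whole pipeline is testable without external data.

A command-line interface wraps the same functions:
`exec/splicescreen scan|splice-score|screen|ancestral-scan|kinetics-fit|simulate`.

## Worked example

Train splice-site models, simulate a four-member family in which three
members carry a weak acceptor plus a planted `GAAGAA` enhancer that the
fourth (strong-acceptor) member lacks, and screen it:

```r
library(splicescreen)

models <- list(
  acceptor = default_site_model("acceptor", n_train = 2000, seed = 100),
  donor    = default_site_model("donor",    n_train = 2000, seed = 101)
)
fam <- sim_paralog_family(
  seed = 42, n_members = 4,
  planted = tibble::tibble(member = c("m1", "m2", "m3"),
                           hexamer = "GAAGAA", codon = 10L),
  acceptor_strengths = c(m1 = "weak", m2 = "weak", m3 = "weak"),
  models = models
)
cfg <- screen_config(ese_hexsets = list(hexamer_set("enhancers", "GAAGAA")),
                     site_of_interest = "acceptor")
reports <- screen_family(unname(fam$records), models, cfg)
flatten_reports(reports)[, c("weak_member", "strong_member", "strength_weak",
                             "strength_strong", "ese_spans", "diff_list")]
#> # A tibble: 3 × 6
#>   weak_member strong_member strength_weak strength_strong ese_spans    diff_list
#>   <chr>       <chr>                 <dbl>           <dbl> <chr>        <chr>
#> 1 m1          m4                    -9.18            15.1 GAAGAA:28-33 col10:E>F
#> 2 m2          m4                    -4.81            15.1 GAAGAA:28-33 col10:E>F
#> 3 m3          m4                   -13.4             15.1 GAAGAA:28-33 col10:E>F
```

Each report names the weak member, the strong member whose aligned columns
lack the enhancer, the acceptor strengths in bits, the enhancer span
(1-based exon coordinates), and the nonsynonymous difference(s) adjacent to
it — here the engineered E→F change inside the planted motif at codon 10.

Kinetics of an enzyme assayed over 0.01–20 mM substrate (1% simulated
noise, 6 replicates), with efficiency derived from a supplied kcat:

```r
d <- sim_mm_data(Vmax = 0.0751, Km = 0.2239, noise_cv = 0.01,
                 n_replicates = 6, seed = 7)
fit <- derive_efficiency(fit_mm(d, enzyme = "WT PLAP-FLAG"), kcat = 240.4)
glance(fit)[, c("enzyme", "Km", "Km_se", "Vmax", "kcat", "kcat_over_Km")]
#> # A tibble: 1 × 6
#>   enzyme          Km   Km_se   Vmax  kcat kcat_over_Km
#>   <chr>        <dbl>   <dbl>  <dbl> <dbl>        <dbl>
#> 1 WT PLAP-FLAG 0.225 0.00156 0.0753  240.         1.07
```

`Km` is in mM, `Vmax` in µM·s⁻¹, `kcat` in s⁻¹ and `kcat/Km` in s⁻¹·µM⁻¹.

## Notes on packaged data

`inst/extdata/` ships *synthetic* stand-ins for the external motif
resources (four SR-protein-style matrices, a 238-member enhancer hexamer
list, a 103-member scored silencer set), emulating the documented formats
and set sizes; they are not the published motif sets. See
`vignettes/splicescreen-methods.Rmd` for the modelling details and
limitations.
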