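---
title: "Codon usage bias analysis with cubscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias analysis with cubscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubscan)
```

## The problem

Synonymous codons are not used equally. The degree and direction of this
codon usage bias (CUB) in a gene family carries information about the
evolutionary forces acting on it: directional mutation pressure pushes
base composition (and with it third-position codon choice) in a common
direction across all codon positions, while translational or other
selection constrains codon choice independently of composition. `cubscan`
implements the standard battery of CUB diagnostics for a set of coding
sequences (CDS) partitioned into groups (typically taxa), as used in
comparative studies of single gene families across vertebrate classes.

The pipeline is: validate CDS → per-sequence composition and indices →
per-group summaries, regressions, ordination and correlation batteries.

## Sequence validation

A usable CDS must consist only of A/C/G/T, have a length divisible by
three, start with ATG, end with exactly one stop codon and contain no
internal stop. `validate_cds()` applies these rules in a fixed order
(ambiguity → frame → start → stop → internal stop), so a sequence failing
several rules always reports the same rejection reason. Rejections are
data (written to `rejected.tsv` by the pipeline), not errors.

Two conventions fix the counting universe for everything downstream:

* the terminal stop codon is kept in the `coding_sequence` object but
  excluded from all counting — composition, ENC and RSCU are computed on
  sense codons only, matching the 59-codon universe of the RSCU
  ordination (stops and the non-degenerate ATG/TGG carry no synonymous
  signal);
* the initial ATG is included in the counts: it is an ordinary methionine
  codon, and excluding it would bias Met frequency at typical CDS lengths.

## Composition

`composition_profile()` reports base fractions over all sense-codon
positions (`a_pct` … `gc_pct`), the positional G+C fractions `p1`, `p2`,
`p3` (= GC1, GC2, GC3), their first/second-position average `p12`, and
the third-position base fractions `a3`…`c3`. Everything is stored as a
fraction in [0, 1]; report tables rescale to percent. Because each codon
contributes one base per position, `gc_pct == (p1 + p2 + p3) / 3`
exactly — a useful internal check.

## Effective number of codons

`enc_observed()` implements Wright's estimator. For each synonymous
family with observed total $n$ and within-family frequencies $\hat p_i$,
the homozygosity is

$$\hat F = \frac{n \sum_i \hat p_i^2 - 1}{n - 1},$$

families with $n < 2$ or $\hat F \le 0$ are unusable, and class means
$\bar F_k$ over the families of degeneracy $k$ give

$$\mathrm{ENC} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} +
\frac{5}{\bar F_4} + \frac{3}{\bar F_6},$$

with the standard-code degeneracy structure (9 twofold families, Ile as
the only threefold, 5 fourfold, Leu/Ser/Arg sixfold; the constant 2
accounts for Met and Trp). Two numerical conventions matter:

* **capping** — with finite counts $\hat F$ can fall below $1/k$, which
  would let a family contribute more than $k$ effective codons; each
  usable $\hat F$ is floored at $1/k$ and the total is capped at 61, so
  the estimator respects its semantic range [20, 61] and equal usage of
  all 61 sense codons yields exactly 61;
* **missing classes** — an absent threefold mean is imputed as
  $(\bar F_2 + \bar F_4)/2$ (the one imputation with a conventional
  justification, since Ile alone carries that class); if the 2-, 4- or
  6-fold class has no usable family the estimate is reported as `NA`
  with a warning rather than guessed.

`enc_expected(s)` evaluates the composition-only null
$2 + s + 29/(s^2 + (1-s)^2)$ at $s =$ GC3, and `enc_ratio()` the
relative deviation $(\mathrm{ENC}_{exp} - \mathrm{ENC}_{obs}) /
\mathrm{ENC}_{exp}$, whose distribution `enc_ratio_histogram()` bins into
half-open bins aligned on zero (default width 0.05, configurable — the
conventional display does not fix a width).

## RSCU

`rscu()` divides each codon's count by its family's count under uniform
synonymous usage ($n/k$). Values classify as over-represented
(RSCU > 1.6), preferred (1 < RSCU ≤ 1.6), unbiased (= 1) or rare (< 1);
exactly 1.6 is *not* over-represented (the convention is "greater
than"). Unobserved families report 0 for all members rather than NaN.

## Mutation pressure versus selection

Three diagnostics:

* **PR2** (`pr2_point()`): the point (G3/(G3+C3), A3/(A3+T3)); (0.5, 0.5)
  means no asymmetry between complementary bases at the third position.
  By default the biases use all sense codons — the definition is stated
  directly on third-position base fractions — with a fourfold-only
  variant available (`third_position_fractions(fourfold_only = TRUE)`,
  `pr2_mode = "fourfold_only"` in the pipeline) for the stricter reading
  in which position 3 is entirely free of amino-acid constraint.
* **Neutrality regression** (`neutrality_fit()`): OLS of `p12` on `p3`
  across the sequences of a group, with Pearson r. Slope ≈ 1 means
  composition drifts at all positions together (mutation pressure
  dominates); slope ≈ 0 means first/second positions are held fixed
  while GC3 drifts (selection dominates). The regression is fit per
  group.
* **ENC ratio distribution**: values clustered just above 0 indicate
  genes slightly more biased than their GC3 predicts.

## Correspondence analysis

`correspondence_analysis()` implements CA directly: the table is scaled
to proportions, centred by the rank-one independence model, standardised
by row/column masses, and decomposed by SVD; principal coordinates are
mass-rescaled singular vectors scaled by singular values. Total inertia
therefore equals the table's chi-square statistic divided by its grand
total — the property the test suite verifies against an independent
chi-square computation. Following the convention of RSCU-based CoA, the
input is the sequences × 59-codon RSCU matrix (not raw counts; a
counts-based variant sits behind `coa_input = "counts"`), run per group
by default (`coa_scope = "joint"` pools everything and adds group
centroids via `project_groups()`). RSCU rows are not count-like, which
is a known conceptual wrinkle of the convention, accepted here for
comparability with the literature. All-zero codon columns are dropped
before decomposition (their chi-square position is undefined); axis
signs are arbitrary, and all derived summaries are sign-invariant.

## Protein properties

`translate_cds()` maps sense codons through the standard genetic code.
`protein_profile()` reports amino-acid frequencies, GRAVY — the mean
Kyte–Doolittle hydropathy per residue, the universal definition of the
index (negative = hydrophilic/soluble) — and aromaticity, the relative
frequency of Phe + Tyr + Trp.

## Correlation battery

`cor_cell()` computes Spearman (default) or Pearson correlations with
two-sided p-values and significance flags at 0.05/0.01; no
multiple-testing correction is applied, mirroring the conventional
presentation of these tables. Spearman uses average ranks for ties, an
exact p-value for n ≤ 10 without ties and the t-approximation otherwise.
Spearman is the default throughout because it is the only method the
canonical tables name explicitly; a Pearson switch is provided. Zero
variance yields a flagged-undefined cell, and `rscu_gc3_correlation()`
flags codons with invariant RSCU as `uniform` — the blacked-out cells of
the usual heatmap. Group-level correlations are computed within groups
across sequences (the only version with defined p-values at typical
group sizes), not across group means.

## The synthetic generator

`generate_dataset()` produces CDS with the statistical structure the
analysis assumes, so every stage is testable without downloads:

* amino acids are drawn i.i.d. from a usage vector whose default is
  enriched in Leu, Gln and Ser — the profile of forkhead-box proteins
  such as FoxP2 with its polyglutamine tract;
* within each family, codon choice is exponentially tilted on
  third-position G+C, with the tilt solved per sequence (root-finding on
  the expected GC3 given the realised amino-acid counts) so expected GC3
  equals the target; codon counts are then filled by randomised rounding
  of the expected counts, keeping realised GC3 within about ±0.01 of
  target at CDS-scale lengths;
* `bias_strength` concentrates each family on one deterministic
  preferred codon (0 = uniform beyond the GC3 tilt, large values
  collapse the family and drive ENC to 20); the default is 0, so
  synthetic CUB is weak — the regime in which ENC stays high —
  and codon-ending preferences are induced purely by the GC3 tilt;
* regimes: `selection` holds amino-acid usage fixed (GC12 flat while
  GC3 varies; neutrality slope ≈ 0), `mutation` re-tilts the amino-acid
  weights per sequence so expected GC12 equals the GC3 target
  (slope ≈ 1). Amino-acid composition is the only lever on GC12 given a
  fixed genetic code, so the mutation regime is a modelling device, not
  a mechanistic claim about any real gene.

`generate_regime_panel()` bundles four groups emulating a vertebrate
single-gene study: GC3-high fish-like sequences (target 0.632) against
bird- (0.453), reptile- (0.434) and mammal-like (0.490) groups, CDS
lengths of roughly 2,100–2,250 nt with group-specific spreads, all under
the selection regime (the regime consistent with near-zero neutrality
slopes in such data). Under these conditions the fish-like group's
preferred codons are predominantly C/G-ending and the other groups'
A/T-ending, and the GC3 ordering is reproduced at n ≥ 20 per group.

What the generator does **not** emulate: phylogenetic correlation among
sequences (each is drawn independently), within-sequence spatial
structure, dinucleotide/CpG effects, and selection on specific codons.
Passing tests therefore demonstrate the correctness and sensitivity of
the statistics, not biological conclusions about real genes.

A single seeded RNG stream drives all draws; a fixed seed gives
byte-identical FASTA output. `gc3_target = NA` disables GC3 steering
for degenerate-limit experiments.

## Numerical choices and degenerate inputs

* ENC: capping and imputation as above; fewer than 2 codons in every
  family is an error (the estimator is undefined).
* RSCU exactly at a class boundary resolves as documented (1.6 →
  preferred, 1.0 → unbiased).
* PR2 with a zero denominator returns a flagged-undefined point; the
  pipeline excludes it from plots with a warning.
* Neutrality regression requires ≥ 3 points and non-constant `p3`;
  constant `p12` yields slope 0 with undefined r.
* CA drops all-zero columns with a warning, errors on all-zero rows,
  and returns a zero-inertia result (all coordinates 0) for rank-0
  tables; singular values below `1e-12` of the largest are treated as 0.
* Histogram bins are half-open `[edge, edge + width)` with a `1e-9`
  relative tolerance so values sitting exactly on an edge land in the
  upper bin deterministically.

## Problem sizes

The test suite and reproduction script run at deliberately desk-scale
sizes: panels of 20 sequences per group at ~710 sense codons (the
empirical length scale of vertebrate FoxP2-class CDS), 50-sequence
regime-recovery panels, and oracle batteries of 100–1,000 random count
tables. These sizes keep the full suite under a couple of minutes while
leaving the stochastic checks comfortable margins (the regime slopes,
for instance, recover to within ±0.05 at n = 50 against a ±0.1
acceptance band).

## Worked run

```{r, eval = FALSE}
panel <- generate_regime_panel(n_per_group = 20, seed = 42)
files <- tempfile(c("panel.fasta", "groups.tsv"))
write_fasta(panel, files[1])
write.table(data.frame(sapply(panel$sequences, `[[`, "seq_id"),
                       sapply(panel$sequences, `[[`, "group")),
            files[2], sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
run_pipeline(files[1], files[2], "cub_out", make_plots = TRUE)
```

This writes the full report layout (`composition.tsv`,
`group_summary.tsv`, `cub.tsv`, `rscu*.tsv`, `pr2.tsv`,
`neutrality.tsv`, `enc_ratio_hist.tsv`, `coa_*.tsv`, `protein.tsv`,
`aa_usage.tsv`, `correlations/`, `rejected.tsv`) plus `manifest.json`
with MD5 checksums and `run.log`. A thin command-line wrapper with
`analyze`, `synth` and `validate` subcommands ships in
`inst/cli/cubscan.R`.

## Known limitations

* Standard genetic code only; no translation-table variants.
* ENC estimator variants differ across historical tools (treatment of
  rare families, capping); this implementation documents its
  conventions precisely and verifies them against an independent oracle,
  but numeric parity with any particular legacy tool is not guaranteed.
* CA on RSCU inherits the usual caveat that RSCU values are not counts.
* Group-level RSCU classification is a majority vote over per-sequence
  classes, with group-mean RSCU reported alongside; other aggregation
  conventions exist.
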