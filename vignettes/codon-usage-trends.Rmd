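---
title: "Methods: codon-usage trends and host adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-usage trends and host adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codontrend)
```

# The analysis in one paragraph

`codontrend` treats a panel of viral coding regions as a matrix of codon
usage and asks three questions: how biased is each taxon's synonym choice
(RSCU, Wright's Nc), is there a dominant compositional gradient across the
panel (PCA of the RSCU matrix with a correlation screen), and which host
cell type's codon usage do the viruses track (Pearson correlations compared
with Hotelling's dependent-correlation test)? The motivating system is the
primate lentiviruses, whose A-rich genomes push third-position composition
towards A/T and away from the usage of most host genes.

# Codon-level statistics and their conventions

**The 59 synonymous codons.** All usage statistics are defined over the 61
sense codons minus ATG and TGG, whose amino acids admit no synonymous
choice; 18 amino-acid families remain, with degeneracies 2 (9 families), 3
(Ile), 4 (5 families) and 6 (Leu, Ser, Arg), summing to 59.

**Counting.** Sequences are read in frame; a triplet containing any
non-ACGT symbol is skipped whole and tallied (partial counting would
distort composition denominators). Stop codons are tallied separately and
never enter usage statistics. The default stop policy accepts a single
terminal stop per gene piece and raises an error on internal stops, because
an internal stop in a declared coding region indicates a frame or
coordinate error, not data to be averaged over. Region extraction validates
each manifest interval separately, so the terminal stop of an upstream gene
is never misread as an internal stop of the concatenation. Gene-terminal
stops are thus stripped from the statistics; on coding complements of
thousands of codons the effect is negligible, and it is documented rather
than configurable.

**RSCU.** `RSCU(c) = (N_c/N_a) × D`. Families with `N_a = 0` are flagged
`undefined` and carry a sentinel 0; every downstream correlation excludes
such entries pairwise instead of treating the 0 as an observation, because
an injected zero is pure noise in a Pearson r. `rscu_matrix()` exposes the
flagged entries as `NA` for exactly this reason.

**Wright's Nc.** Per family, the bias-corrected homozygosity
`F̂ = (nΣp² − 1)/(n − 1)` (families with `n < 2` or `F̂ = 0` excluded);
class means over degeneracy classes; `Nc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ +
3/F̄₆`. Two conventions matter:

* Six-fold families are kept whole, not split 4+2 — the 2+9+1+5+3 = 20
  class structure of the formula requires it.
* The finite-sample estimator slightly overshoots the theoretical maximum
  (uniform usage of all 59 synonyms at depth 1000 gives ≈ 61.04), so the
  reported value is capped into [20, 61]; the raw value is retained in
  `nc_raw`. If the single three-fold family (Ile) is unobserved, F̄₃ is
  imputed as the mean of F̄₂ and F̄₄; any other empty class is an error.

A consequence worth stating plainly: because F̂ carries an O(1/n) sample-
size correction, Nc is only asymptotically scale-invariant. Multiplying all
counts tenfold moves Nc by roughly 1/n per family — a few tenths at depths
of hundreds per family, below 0.05 only once families are observed
thousands of times. The test suite asserts this convergence rather than a
fixed small bound at low depth, which the estimator cannot honour.

**Positional composition.** Percent A/T/G/C at a codon position,
occurrence-weighted (each counted codon occurrence contributes its base),
under an explicit inclusion rule. Third and second positions use all 59
synonyms. The first position excludes AGA, CGA, AGG, CGG (Arg) and TTA,
CTA, TTG, CTG (Leu): these are the only synonym pairs differing at position
one, so removing them makes every retained first position strictly
non-synonymous. Brute-force enumeration over the 59 synonyms × 3
alternative first bases gives 8 silent events out of 177 (≈ 4.5%), and the
8 codons involved are exactly the exclusion set; the tests pin this
enumeration.

**Amino-acid composition** is reported over the 18 degenerate families
only, with Met/Trp excluded from numerator and denominator, so an
18-dimensional profile can never be silently compared with a 20-dimensional
one.

# Trend extraction

**PCA preprocessing.** The default is column-centred, unscaled covariance
PCA: RSCU values (and composition percentages) already share a scale, and
scaling to unit variance would inflate the influence of rarely varying
codons. Both flags are exposed because variance fractions are
preprocessing-sensitive; any cross-study comparison of "PC1 explains X%"
should state the choice. Codons as observations (the transposed
orientation) are supported via an explicit `transpose` argument — the
orientation is never inferred from the matrix shape.

**Sign convention.** A principal component's sign is arbitrary, which makes
"PC1 increases along the gradient" irreproducible unless fixed.
`orient_component()` negates a component if and only if its correlation
with an external anchor covariate is negative; the fit anchors RSCU-space
PC1 to third-position A+T content and amino-acid-space PC1 to Ile content.
The operation is idempotent and recorded in the result.

**The screen.** Each codon's RSCU is correlated with the PC1 score;
`t = r√(n−2)/√(1−r²)`; codons with |t| strictly above the cutoff are
partitioned by the sign of r. The default cutoff 4.84 is taken as a given
constant (a conventional p = 1e-5 threshold at panel sizes near 60–100
observations); it is deliberately not re-derived from a p-value, since the
degrees of freedom such a derivation should use (codons vs taxa) is
ambiguous, and the constant is what practitioners quote. Perfect
correlations are reported with the sentinels t = ±Inf, p = 0 rather than
errors, because degenerate fixtures legitimately produce them.

A caveat the package states rather than hides: the screen correlates PC1
with the very columns PC1 was computed from. On a panel with no real
gradient, PC1 overfits sampling noise (the leading sample eigenvalue of a
59-dimensional noise matrix at 50–100 observations is inflated), so a few
codons exceed even a 4.84 cutoff essentially always. The screen's cutoff
semantics are calibrated for exogenous scores — against an independent
score vector, an i.i.d.-noise feature passes with probability ≈ 1e-5 — and
the suite demonstrates both behaviours. Screen results on weak gradients
should therefore be read as descriptive, not as selection-corrected
inference.

# Inferential toolkit

* **Pearson + t** (`pearson_with_t`): df = n − 2, two-sided p, pairwise
  exclusion of incomplete pairs.
* **Hotelling (1940) t** for two correlations sharing a variable:
  df = n − 3; exactly antisymmetric in (r₁₂, r₁₃); zero at equality;
  requires the correlation triple to be positive definite. Williams'
  modification — better calibrated for small n in the literature — is an
  option; the default follows the 1940 form because the Monte-Carlo
  calibration in the suite (n = 59, 10,000 null replicates) shows its
  type-I error within 0.05 ± 0.01 at this panel size.
* **2×2 chi-square**: Pearson form, df = 1, no Yates correction by default
  (with family counts in the thousands the correction is negligible); a
  flag enables it. Group amino-acid comparisons pool raw codon counts over
  the group's taxa ("overall content"); a `pooling = "mean"` variant scales
  mean per-taxon percentages instead, since group content can reasonably be
  read either way, and the report shows pooled and mean-of-taxa A+T3 side
  by side.
* **Two-sample t**: pooled-variance Student by default, Welch optional.
* No multiple-testing machinery is applied anywhere; the screen's 4.84
  cutoff is the only selection device, and p-values are reported raw.

# The synthetic panel generator

`generate_panel()` emulates exactly the structure the analysis assumes, so
every pipeline stage is testable without downloads: groups with target
third-position A+T fractions (within each family, the probability mass on
A/T-ending synonyms equals the target, making the expected occurrence-
weighted A+T3 exact regardless of amino-acid composition), an optional
multiplicative amino-acid shift per group, i.i.d. codon sampling, a
terminal stop, and FASTA/manifest output that passes through the package's
own readers. `lentivirus_panel_spec()` fixes the study-shaped default: 8
groups spanning A+T3 0.654 → 0.704 evenly (the observed span from
SIV-infecting-monkey panels to pandemic HIV-1 group M), 54 taxa of 8000
codons each (the scale of a full non-overlapping coding complement), and an
Ile/Ser-rich, Tyr/Leu-adjusted amino-acid base whose four anchor shares
(6.7/4.4/3.7/8.6%) match reported lentiviral coding regions.
`generate_host_table()` draws a 10⁶-codon multinomial table at a target
A/T-ending share — 0.534 emulates a monocyte-like table, 0.452/0.467
lymphocyte-like ones.

What the generator does **not** emulate, deliberately: phylogenetic
correlation between taxa (every taxon is an independent draw), positional
autocorrelation, RNA-structure constraints (such as conserved structured
elements or "no-A" positions), overlapping genes, and indels. Passing tests
therefore certify the statistical machinery on panels with the assumed
structure; they do not certify that real panels meet those assumptions —
in real data, phylogeny alone can produce gradients, and structured RNA
elements (which is why manifests support exclusion spans, e.g. for the RRE)
can distort local composition.

# Numerical and interface choices

* Manifest coordinates are 1-based inclusive on the forward strand (GenBank
  convention); all internal arithmetic is 0-based half-open. Antisense ORFs
  are out of scope.
* Interval lengths must be divisible by 3 after exclusion subtraction;
  anything else is rejected rather than trimmed.
* Host tables must contain all 59 synonymous codons exactly once; ATG/TGG
  and stops are dropped with a message; counts are converted to RSCU
  internally. For RSCU-only tables the A/T-ending share is the
  equal-family-occupancy value (mean over families of the A/T RSCU mass
  over D), since occurrence weighting needs counts.
* Report tables are written with 10 significant digits and a header
  carrying the package version and a configuration fingerprint; re-writing
  the same fit is byte-identical. Host tables round-trip at full precision
  (`%.17g`).
* All generator randomness flows through explicit seeds, and the generators
  restore the session RNG state, so a fixed spec yields byte-identical
  FASTA/manifest files anywhere.

# Problem sizes used in the checks

The suite's heavier checks run the full pipeline on generated panels at the
study scale — 54 taxa × 8000 codons for gradient recovery and host ranking,
20 replicate seeds for the rank-recovery and null-screen properties, and
10,000 Monte-Carlo replicates for the Hotelling calibration — sizes chosen
to mirror the panels the analysis is designed for while completing in
minutes on a single CPU.

# Known limitations

* Nc follows Wright (1990) exactly; later corrections (e.g. for background
  nucleotide composition) are not implemented.
* The screen's endogeneity (above) means its false-positive behaviour under
  a true null is optimistic; treat small selected sets near the cutoff with
  caution.
* Codon adaptation indices (CAI, tAI) and dinucleotide odds ratios are out
  of scope, as is any phylogenetic inference: the package quantifies
  compositional trends, it does not test evolutionary models that might
  explain them.
* PCA variance fractions depend on the centre/scale choice; comparisons
  against values computed elsewhere are meaningful only under the same
  preprocessing.
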