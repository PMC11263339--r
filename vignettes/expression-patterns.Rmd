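---
title: "Classifying sex- and tissue-associated expression and its misregulation in intersex backcrosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying sex- and tissue-associated expression and its misregulation in intersex backcrosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intersexpr)
```

## The analysis in one paragraph

Interspecies backcrosses between *Aedes aegypti* (Uganda strain, "U") and
*Ae. mascarensis* ("M") yield genetically male mosquitoes with variable
feminization — intersexes carrying ovarian tissue, spermathecae, or
malformed male accessory glands. `intersexpr` takes a gene-by-sample count
matrix over the 14-group design (U, M and the backcross UUM; males, females
and intersexes; reproductive organs and carcass; three biological
replicates per group, 42 samples), quantifies expression as FPKM, calls
differential expression between pairs of groups with a negative-binomial
exact test, applies a threshold decision tree to sort genes into low /
unbiased / biased / specific categories per comparison, combines
comparisons into five expression clusters and six sex-by-tissue gene
groups, and finally labels each group member's behavior in intersexes as
No change, Upregulation, Downregulation or Other across five
normal-versus-intersex comparisons. A companion module builds contingency
tables from per-individual phenotype records and tests the association
between pupal and adult feminization with Pearson chi-square and
likelihood-ratio G statistics.

## Quantification

FPKM for gene $g$ in sample $s$ is

$$\mathrm{FPKM}_{gs} = \frac{c_{gs} \cdot 10^9}{L_g \, N_s},$$

with $c_{gs}$ the fragment count, $L_g$ the transcript length in bp and
$N_s$ the library size. By default $N_s$ is the column sum over the
supplied gene universe, which keeps the pipeline self-contained; when a
total-mapped-fragments figure exists it can be passed explicitly
(`library_sizes`), and the two conventions differ by a dataset-wide factor
equal to the fraction of the library assigned to the universe. All
low-expression thresholds are applied to the **group mean** FPKM
(arithmetic mean over replicates), because the classification makes one
decision per gene per comparison, not per replicate. Genes missing from the
length table are dropped with a warning rather than given a default length
— a silently wrong length corrupts FPKM by an arbitrary factor.

## The differential-expression test

The classification rules consume, per gene and comparison: a fold change,
a BH-adjusted significance call, and the two group means. The test behind
the significance call is authored in the package and is deliberately
self-contained; it follows the classical exact conditional strategy for
negative-binomial counts:

1. **Normalization.** The samples of the two groups are rescaled by total
   counts to their geometric-mean library size and rounded. Total-count
   scaling is the smallest defensible choice; trimmed-mean or
   median-of-ratios normalization can be slotted in upstream by passing
   adjusted counts, but is out of scope.
2. **Dispersion.** Per gene, a method-of-moments estimate on the
   normalized counts, $\hat\phi_g = \max(0, (s^2 - \bar m)/\bar m^2)$,
   pooling within-group variances; then shrinkage towards the common mean
   dispersion: $\phi^*_g = w\,\bar\phi + (1-w)\,\hat\phi_g$ with $w = 0.7$.
   At three replicates the raw moments are extremely noisy (coefficient of
   variation near 100%); the common component carries most of the
   information, while the per-gene 30% share lets strongly atypical genes
   move the estimate. Designs with a single replicate in both groups are
   rejected with instructions to supply a fixed dispersion.
3. **Exact test.** Conditional on the gene's total $t$ across both groups,
   the group-A sum follows a distribution that is free of the unknown mean
   when both groups share $\phi$: with $r_A = n_A/\phi$, $r_B = n_B/\phi$,
   $$P(Y_A = a \mid t) \propto \binom{a + r_A - 1}{a}\binom{t - a + r_B - 1}{t - a},$$
   the negative-hypergeometric split law, computed in log space and
   normalized. The two-sided p-value sums all splits whose probability does
   not exceed the observed one (ties admitted with a relative tolerance of
   1e-10 on the log scale). $\phi = 0$ uses the binomial (Poisson) limit.
   All-zero genes get p = 1 and an `all_zero` flag.

The fold change is computed on prior-damped group means,
$\log_2((m_B + c_0)/(m_A + c_0))$ with $c_0 = 0.25$ FPKM, so that silent
groups give large but finite fold changes. BH adjustment is applied within
each comparison separately, never pooled across comparisons, matching the
per-analysis significance convention of the classification rules.

Exact numerical agreement with any external DE package is *not* claimed —
dispersion estimation and normalization details differ between
implementations. Agreement is asserted where it matters for this pipeline:
the test matches an exhaustive enumeration oracle to 1e-12 at small totals,
holds its nominal type-I error within a factor of two on 5,000 simulated
null genes, and the downstream classification recovers planted truth at
strong effect sizes (see the acceptance script). Externally produced DE
tables can be ingested as-is through `read_de_table(col_map = ...)` and
drive the identical downstream rules.

## Thresholds and the decision tree

Three thresholds, all positive, with the field-standard defaults:

| knob | default | units | role |
|---|---|---|---|
| `fpkm_low` | 1 | FPKM | below this (group mean) a gene counts as unexpressed |
| `lfc` | 2 | log2 units | four-fold change required to call bias |
| `fdr` | 0.05 | proportion | BH-adjusted significance level |

Per comparison the tree is: both means under the floor → **low**; else
FDR > 0.05 or |LFC| ≤ 2 → **unbiased**; else lower mean under the floor →
**specific**; else **biased**. Two readings were fixed deliberately:
"expressed above 1 FPKM" in the unbiased rule is read as "not low" (at
least one group mean at or above the floor), since otherwise genes with one
mean just under 1 would be unclassifiable; and the absolute fold change is
used throughout, so orientation affects only the direction of a call,
never its category. The published downregulation rule contains an evident
sign slip (as printed it would swallow the upregulation region); the
package uses the symmetric form $\mathrm{LFC} \le -2$, consistent with the
open no-change band $-2 < \mathrm{LFC} < 2$.

## Clusters, the combine rule, and the six groups

Five clusters are built from pure-species comparisons only:
REPRODUCTIVE_SEX and CARCASS_SEX (male vs female within each species, two
comparisons each), REPRODUCTIVE_SPECIES and CARCASS_SPECIES (U vs M within
each sex, two each), and TISSUE (reproductive vs carcass within each
species-sex pair, four).

How to combine a cluster's comparisons is genuinely open — the choice is
exposed (`rule = "all"` or `"any"`) with **all-consistent** as the
conservative default: every informative comparison must call the gene
specific (→ `<side>_specific`) or specific/biased with at least one biased
(→ `<side>_biased`), always with agreeing directions. Two refinements
matter in practice:

* Comparisons that call the gene **low are uninformative, not
  disqualifying**. A female-specific, ovary-specific gene is unexpressed in
  males in *both* tissues, so the male halves of the TISSUE comparisons are
  necessarily low; demanding a specific call there would make the joint
  sex-by-tissue groups structurally empty. Only genes low in *every*
  constituent comparison are excluded from the cluster outright.
* Conflicting directions always yield no membership, and are the reason a
  gene can be specific in one species yet absent from the cluster.

The six gene groups cross the tissue-matched sex cluster with TISSUE:
{sex-specific, sex-biased} × {tissue-specific, tissue-biased,
tissue-unbiased}. **Tissue-unbiased** is defined as "in no TISSUE subtype
while not low there" — the only reading that makes the six groups
exhaustive over the non-low sex-associated genes. Genes whose TISSUE
subtype points at the other tissue are out-group for the setting under
analysis and are excluded, as are genes low in the relevant comparisons.

## Intersex pattern classification

For a chosen tissue and reference sex the five comparisons are, in order:
U vs UUM, M vs UUM, UUM vs UUMix, U vs UUMix, M vs UUMix, always oriented
second-over-first so that negative fold changes in the last three mean
lower in intersexes. Female-associated groups are profiled against normal
females of U, M and UUM; male-associated groups against normal males
(configurable). Elementary calls use the same thresholds; the pattern label
is No change (all five quiet), Up-/Downregulation (first two quiet, last
three unanimous), else Other. The label is sensitive only to the
first-two/last-three block structure: permutations within a block never
change it.

## What the simulator emulates, and what it does not

The generator exists so every downstream rule can be validated against
planted truth. It emulates:

* the 14-group × 3-replicate design (`default_design()`);
* negative-binomial counts with mean
  $\mathrm{FPKM} \cdot L_g \cdot N / 10^9$ and variance
  $\mu + \phi\mu^2$, one documented RNG stream per matrix, seed required;
* planted classes mirroring the rule vocabulary (low, unbiased,
  sex/species/tissue-specific/-biased), with sex-class genes carrying a
  secondary tissue axis so all six joint groups receive members, and an
  intersex behavior (`no_change` copies the reference-sex backcross mean,
  `down`/`up` divide/multiply it by the planted fold change, `other`
  perturbs the normal-backcross mean so the first two comparisons already
  deviate);
* background calibration: the unbiased background mean is set so the
  expected library composition satisfies
  $\sum_g \mathrm{FPKM}_g L_g = 10^9$, making planted FPKM values
  recoverable from the counts themselves rather than only up to a factor;
* phenotype records whose defaults reproduce the published UUM backcross
  marginals — pupa-type counts (21, 23, 16), intersex-adult probabilities
  5/21, 18/23, 15/16, two-MAG probabilities 16/21, 5/23, 1/16, with mass
  split evenly inside the normal (classes 1–2) and intersex (3–5) blocks
  because only the marginals are published.

It does **not** simulate reads, alignment or counting noise, GC or length
bias, batch effects, library-preparation artifacts, or correlated genes;
dispersion is a per-gene constant, not a mean-dependent trend. Passing
tests therefore demonstrate that the rules and statistics are implemented
correctly and are well-calibrated under the model's own assumptions — not
that the model captures every property of real mosquito libraries.
Intersex biological variance is unknown territory; the generator exposes
$\phi$ per gene rather than guessing a separate intersex value.

## Numerical choices and degenerate inputs

* Exact-test tie tolerance 1e-10 (relative, log scale); probabilities
  normalized by log-sum-exp; p-values clamped to (0, 1].
* Threshold comparisons use the operators exactly as stated (≤, ≥, strict
  band), so boundary cases are deterministic: LFC = 2 with FDR = 0.05 is an
  up call, LFC just inside the band is no-change regardless of FDR.
* All-zero genes: p = 1, flagged, classified low.
* Contingency tables: no continuity correction; zero-expectation cells are
  dropped from X² with a warning; zero-observed cells contribute 0 to G;
  1×k tables are rejected (zero degrees of freedom); proportions are
  reported to two decimals.
* Writers emit UTF-8, "." decimals, no scientific notation for counts;
  membership serializes as 0/1 presence columns per (cluster, subtype).

## Problem sizes

The test suite and acceptance script run simulations scaled to keep the
whole battery in the tens of seconds while leaving wide power margins:
planted-recovery runs use 800–1,500 genes at a nominal library of
1.5 × 10⁶ fragments (the planted high side, 400 FPKM, then yields hundreds
of counts per replicate and the biased low side ~10, ample for six-log2
effects); null calibration uses 5,000 genes at three-versus-three
replicates; Monte-Carlo checks of planted FPKM recovery use 300 replicates
per group, where the replicate-mean coefficient of variation
($\sqrt{\phi}/\sqrt{n}$ at $\phi = 0.1$) is below 2%. At three replicates
that CV is ~18%, so per-gene mean recovery within 5% is a many-replicate
property by construction, not a three-replicate one.

## Known limitations

* The exact test conditions on totals after rounding rescaled counts;
  for very small libraries the rounding can shift a split by one unit.
* The all-consistent combine rule is conservative: a gene specific in one
  species and unbiased in the other is dropped, which undercounts shared
  biology when power differs between species.
* BH per comparison means a gene's FDR is not comparable across
  comparisons with different gene universes.
* The printed association p-values for the full pupa-type-by-class tables
  depend on per-class counts that are not published in the running text;
  the package computes its statistics from whatever records are supplied
  and makes no claim to reproduce numbers whose inputs it cannot see.
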