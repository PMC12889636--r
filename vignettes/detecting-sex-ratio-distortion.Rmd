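---
title: "Detecting sex-ratio segregation distorters in pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-ratio segregation distorters in pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Segregation distorters (meiotic drivers) are selfish genetic elements that
bias their own transmission. A distorter on a sex chromosome leaves a
visible fingerprint: skewed offspring sex ratios. Individual human families
are far too small to demonstrate distortion by offspring counting, and
genotype-based scans are plagued by genotyping-error false positives. This
package takes the genotype-free route: it treats the *recorded sex* of each
individual in a deep, multi-generation pedigree as a faithful marker of
sex-chromosome transmission, and looks for *heritable* sex bias — bias that
tracks lines of descent rather than scattering randomly through the
genealogy.

A Y-linked distorter is the clean case: the Y passes father to son every
generation, so all carriers of one distorting Y form a single patriline and
each carrier father's offspring sex ratio is informative. An X-linked
distorter only distorts through males (carrier males produce mostly
daughters), skips generations, and is confounded by X-linked recessive
lethals that also deplete sons; the package models both, but the male-bias
mode is the one with real discriminating power, and every downstream lineage
statistic (the TDT scan) is built on patrilines.

## The carrier model

Each individual $i$ has a latent binary carrier state $C_i$. The value
$C_i = 0$ encodes the null model (Mendelian sex: every child is male with
probability $1/2$, nothing is heritable); $C_i = 1$ encodes the distortion
model. The two models compete inside one Bayesian network whose backbone is
the pedigree itself:

* **Founder prior.** Roots receive $P(C=1) = \pi$ (`allele_freq`, default
  0.01). In male-bias mode a root is anyone without a recorded father, and
  only males can carry (a female's Y-carrier probability is identically
  zero); in female-bias mode a root is anyone with no recorded parents.
* **Sex evidence.** A child's observed sex depends on the *father's*
  carrier state only: $P(S = \text{favored} \mid C_f = 1) = p$
  (`penetrance`, default 0.90) and $1/2$ otherwise. Mothers never distort;
  in the X case this encodes that a distorting X only acts in males.
* **Inheritance.** In male-bias mode a son inherits the carrier state of
  his father up to the de novo rate $\mu$ (default $10^{-6}$):
  $P(C_c = 1 \mid C_f) = (1-\mu) C_f + \mu (1 - C_f)$, and daughters never
  carry. In female-bias mode a carrier father transmits to every daughter
  (probability $1-\mu$), never to sons; a carrier mother transmits to each
  child with probability $\tfrac12(1-\mu)$; and the three acquisition
  routes (father, mother, de novo) combine as independent events,
  $P(C_c=1) = 1 - (1-t_f)(1-t_m)(1-\mu)$. The female carrier state is
  capped at one copy — at $\pi = 0.01$ homozygotes are negligible, and the
  cap keeps the state binary; this is an acknowledged approximation.
* **Missing parents** are treated as non-carriers (out-of-pedigree spouses
  are overwhelmingly non-carriers at these frequencies); individuals of
  unknown sex contribute no sex evidence and are never assumed to be male
  for Y transmission.

For a single father with $m$ favored and $f$ other children and no further
ancestry, one Bayes update gives the closed form implemented in
`single_sibship_posterior()`:

$$P(C=1 \mid m, f) =
  \frac{\pi\, p^m (1-p)^f}{\pi\, p^m (1-p)^f + (1-\pi)\, 2^{-(m+f)}}.$$

With the defaults, four sons of four give 0.0959 while two of four give
0.00131 — a father of four sons is a far better distorter candidate than a
father of two sons and two daughters, even though both sibships have the
same size.

## Inference

`run_warp()` computes every individual's marginal carrier posterior given
*all* observed sexes by sum-product belief propagation on a factor graph
with one factor per nuclear family. Messages sweep leaves-to-roots and
roots-to-leaves in generation order, so information from a founder reaches
the last descendant and vice versa.

Two structural facts matter. In male-bias mode the mother's state is
irrelevant, families are keyed by father alone, and the factor graph is a
*forest* — inference is exact on every pedigree, inbred or not, and the
first sweep already fixes the answer (the second confirms convergence). In
female-bias mode families are keyed by the parent couple; the graph is a
tree for outbred pedigrees (exact inference) and loopy when there is
inbreeding or systematic sibling-exchange marriage, in which case the
sweeps iterate. Numerical choices: convergence is declared when no
posterior moves by more than `tol` ($10^{-9}$) between sweeps, with a
`max_sweeps` cap of 100; non-convergence sets a flag rather than throwing;
an optional `damping` factor (the weight of the fresh message, default 1 =
undamped) helps looped pedigrees settle; messages are normalised at every
step and family products are rescaled jointly to avoid underflow in very
large sibships. `exact_posterior_enumeration()` computes the same marginals
by summing over all $2^n$ carrier configurations ($n \le 20$) and serves as
the independent oracle: the test suite requires agreement within $10^{-9}$
on loop-free pedigrees in both modes.

### Choosing the penetrance: the grid sweep

The scorer is a *detector*, not a test, and its penetrance parameter is
deliberately fitted: `sweep_parameters()` reruns the scorer over a grid
(the canonical grid spans penetrances 50–99%) and reports, per combination,
the single most confident individual. The reconstructed focal family makes
the point concretely: its overall bias is about 2:1 (67.4% male), so under
the default 90% penetrance the distortion model fits *worse* than the null
and no individual crosses the 40% clustering threshold, while the grid
selects a penetrance near 0.68 and lifts the top patriline father above
0.7. Because the significance machinery (below) uses the same parameters
for the true and permuted data, this fitting step does not invalidate the
permutation p-values. One documented wrinkle: the canonical sweep grid for
allele frequency spans 0.001 down to $10^{-6}$, yet the stated chosen
operating value is 0.01; the package defaults follow the chosen value and
`sweep_parameters()` accepts whatever grid the caller specifies.

## Significance: whole-pedigree sex permutation

Extreme families exist by chance in any large genealogy. The null that
respects everything except heritable sex bias is: keep the tree topology
fixed, permute the multiset of sex labels uniformly, and rescore. Permuted
pedigrees may put a female label in a father role — that is intentional
(it makes the null *more* permissive, hence conservative) and is why the
pedigree container has a permissive validation mode. Three empirical
p-values are computed by `run_permutation_suite()`, all with strict
"greater than" counting (so $p = 0$ is attainable; an add-one convention is
an option):

* **max-likelihood** — fraction of permuted pedigrees whose *best*
  individual beats the true best: a family-wise test.
* **z-max** — the same after per-run standardisation of all posteriors,
  robust to level shifts between runs.
* **focal rank** — the rank of one named individual (default: the
  *putative originator*, the patriline root of the argmax individual in
  male-bias mode, the max-posterior ancestral founder in female-bias mode)
  in the true versus permuted runs. Had the focal individual been the
  argmax itself, its true rank would be 1 and the p-value identically
  zero, which is why the originator is the sensible focal choice. Because
  the focal individual is still *selected* using the true run, this
  statistic deliberately ignores multiple testing and is anti-conservative
  under the null; it is reported as corroboration, never as the headline
  test, and the package's null-calibration checks are therefore stated on
  the max-likelihood and z-max statistics.

## Lineage TDT, FDR and the Monte Carlo family test

`patrilineal_lineages()` extracts every Y lineage (a fatherless male root
plus all males reachable through father–son links; in permissive permuted
pedigrees the father *role* defines the patriline regardless of the
permuted label). Every child of a lineage member is one informative
transmission. `scan_lineages()` applies the classic transmission
disequilibrium chi-squared — $(m - n/2)^2/(n/2) + (f - n/2)^2/(n/2)$, 1 df,
upper tail, no continuity correction (the published worked example
$p = 0.00102$ for 60/29 matches the uncorrected statistic) — to every
lineage, keeps Benjamini–Hochberg FDR correction to lineages with more than
75 transmissions (small families are uninformative; the cutoff is the
published, admittedly arbitrary, one, and strict), and reports the 99%
binomial envelope (`qbinom` at 0.005/0.995) for plotting male proportion
against lineage size.

`monte_carlo_family()` is the numerical twin of the TDT for one family:
draw the $n$ transmission sexes as fair coins, 10,000 times, and count
replicates at least as extreme (two-sided, $|k - n/2| \ge |m - n/2|$,
matching the two-sided chi-squared; a one-sided option exists). The
simulation randomises the transmission sexes directly rather than
re-deriving patriline membership from a fully permuted family, because
"families of equal size" with a fixed transmission count is the only
reading that is well defined without the family's full internal structure —
and it converges to the exact two-sided binomial tail, which for 60 of 89
is 0.00134 (printed estimates near 0.00138 are within Monte Carlo error).

## The synthetic generator, and what passing tests do and do not show

No real genealogy ships with this package, so `generate_pedigree()` stands
in for one: founder couples, Poisson offspring counts (mean 2.5 by default,
echoing large historical families), out-of-pedigree spouses (probability
0.8 per child), and an optionally planted distorter whose mechanics mirror
the carrier model exactly (carrier fathers produce the favored sex with the
planted true penetrance). Ground-truth carrier labels come back with the
pedigree. `focal_family_fixture()` deterministically reconstructs the focal
family's printed totals — 33 transmitting fathers, 89 transmissions, 60
male, 29 female, seven generations, with the quoted sub-sibships (2 sons;
5 of 6; 1 of 1; 8 of 11) embedded verbatim; the padding sibships are
synthetic, keep every padded sibship no more male-biased than the printed
ones, and are documented as a totals-matching reconstruction, not the real
(unpublished) family structure.

The generator emulates topology, fair-coin sexes and planted heritable
bias. It does *not* emulate demographic realism — mortality, remarriage,
migration, record-linkage error, secular family-size trends, or recording
biases between sons and daughters. Passing calibration tests therefore
show the statistics behave correctly under the stated null and power
models, not that real genealogies are free of the systematic biases the
null does not contain.

Problem sizes used by the test suite (chosen to make the sampling
distributions meaningful at desk scale): the oracle-equivalence property
uses 100 random loop-free pedigrees of up to 12 individuals; null
calibration uses 500 simulated null lineages (sizes 76 + geometric, mean
160 — all above the size filter, and the size mixture smooths the
discreteness of binomial p-values) with 20 seeded runs of a
Kolmogorov–Smirnov check against uniformity at the 1% critical value, plus
200 independent ~400-person null pedigrees (12 founder couples, five
generations) with 99 permutations each; the power property plants a
penetrance-0.9 Y distorter in seven-generation pedigrees and conditions on
at least 80 carrier transmissions (datasets not meeting the condition are
regenerated from the next derived seed), requiring the argmax individual to
be a true carrier in at least 18 of 20 datasets.

## Configuration, reproducibility, interfaces

All randomness flows from explicit integer seeds: the simulator from its
config seed, permutation and Monte Carlo replicate streams from
deterministically derived child seeds, and belief propagation itself is
deterministic and needs none. `run_full_pipeline()` (or the installed
`drivescan` command-line script: `simulate`, `run`, `permute`, `cluster`,
`tdt`, `montecarlo`, `sweep`, `pipeline`) writes every stage as plain TSV
plus a YAML manifest of all parameters and seeds, sufficient to re-run any
stage in isolation; the command-line tools accept a YAML config file whose
keys mirror the flags. Logging goes to standard error, data to files.

## Known limitations

* Autosomal distorters are out of scope: without genotypes there is no
  autosomal marker to track.
* Female-bias mode is honest but weak, for the biological reasons above;
  its posteriors are exact only on loop-free pedigrees.
* The one-copy cap on the X carrier state ignores homozygous females.
* The TDT treats transmissions within a lineage as independent fair coins
  under the null; overlapping lineage membership (identical-by-descent Y
  chromosomes not captured by the recorded pedigree) is invisible to it.
* The focal-rank permutation statistic is anti-conservative by
  construction and should be read as corroboration only.
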