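---
title: "Methods: sex-specific crossover rates and interference from RAD tags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-specific crossover rates and interference from RAD tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design: two pseudo-testcrosses in one F1 population

In an outbred F1 cross, a SNP heterozygous in one parent and homozygous in
the other segregates 1:1 in the progeny and carries crossover information
for the heterozygous parent only. `radxo` works with RAD tags that carry
*both* configurations — one ab×aa (female-informative) and one aa×ab
(male-informative) SNP less than 1 kb apart — so the two parents can be
compared over the *same* genomic intervals, as if two reciprocal backcross
populations had been genotyped at identical positions. Tags are spaced more
than 100 kb apart so that crossovers between adjacent tags are observable
in a population of a few hundred progeny.

Because the linkage phase of an outbred parent is unknown, every estimator
in the package first resolves phase by maximum likelihood (the
recombinant-minority rule) and then works on phase-canonicalised counts.

## Two-point model

For two same-parent SNPs the progeny genotype pairs fall into four classes
with multinomial probabilities, under coupling,
$((1-r)/2,\; r/2,\; r/2,\; (1-r)/2)$, where $r$ is the crossover rate of
the interval in that parent; repulsion is the same model with the class
labels of one marker swapped. The MLE is the recombinant fraction
$\hat r = (n_{12}+n_{13})/n$. Phase inference picks the labelling with
$\hat r \le 0.5$, with ties (exactly 0.5) reported as coupling and flagged
unlinked.

Equality of the female and male rates over an interval is tested with the
likelihood ratio
$LR = 2[\ell(\hat r_f) + \ell(\hat r_m) - \ell(\hat r)]$, where
$\hat r$ pools both parents' recombinant counts; $LR$ is referred to
$\chi^2_1$. Boundary estimates ($\hat r \in \{0, 0.5\}$) use the
$0\log 0 = 0$ convention. Runs of two or more adjacent significant
intervals are merged into significant regions; isolated significant
intervals are reported separately.

The genome-wide comparison pairs the per-chromosome mean rates in a
two-sided Wilcoxon signed-rank test (exact null distribution for up to 25
untied pairs). `compare_rates()` also offers interval-level pairing: with
few chromosomes the exact chromosome-level test cannot reach $p < 0.05$
(with 5 pairs its smallest two-sided value is $2/2^5 = 0.0625$), so
validation on small synthetic genomes uses the interval-paired variant;
on a 19-chromosome dataset the chromosome-level test is the appropriate
summary.

## Three-point model and the coefficient of coincidence

For two adjacent intervals with rates $r_1, r_2$ and coincidence $C$, the
joint crossover-pattern frequencies are
$r_{11} = r_1 r_2 C$, $r_{10} = r_1 - r_{11}$, $r_{01} = r_2 - r_{11}$,
$r_{00} = 1 - r_1 - r_2 + r_{11}$, and the eight genotype classes at three
same-parent SNPs have probabilities $r_{..}/2$ under coupling–coupling
phases. The MLEs are the marginal recombinant fractions and
$\hat C = \text{(observed doubles)}/(n\,\hat r_1 \hat r_2)$; feasibility
($C \le \min(1/r_1, 1/r_2)$, all class frequencies in $[0,1]$) holds
automatically at the MLE. $C=1$ means independence, $C<1$ positive and
$C>1$ negative interference.

The four phase combinations of the two sub-pairs (CC, RC, CR, RR) reduce to
the canonical coupling–coupling exponents by relabelling het/hom at exactly
one marker: the first marker for RC, the third for CR, the middle one for
RR. These permutations were verified against brute-force likelihood
maximization over all candidate relabellings, and all reported statistics
are invariant to arbitrary single-marker relabellings of the input.

Interference is tested per interval pair with
$LR = 2[\ell(\hat C) - \ell(C = 1)]$ against $\chi^2_1$; significant pairs
are classified negative ($\hat C > 1$) or positive ($\hat C < 1$). The
$\chi^2_1$ reference is an approximation at the boundary $\hat C = 0$: when
the expected double count $n r_1 r_2$ is small (long intervals or small
populations), pairs with zero observed doubles can reach nominal
significance and are always classified positive, so direction tallies at
low double counts carry a boundary artifact that the user should read with
the per-pair expected counts in mind.

The minimum-interval-length (MIL) scan chains each parent's SNPs greedily
left to right so consecutive gaps are at least the MIL (grid default 0.5,
1, 2, 3, 4, 5 Mb), forms overlapping triples, and summarises per parent:
the number of significant pairs, the $\hat C > 1$ / $\hat C < 1$ split,
genome coverage (union of triple spans over genome size), and pairs
significant in both parents. Since the two parents' triples use different
SNPs, "common" pairs are matched by physical overlap of their spans, with
the directional split counting only same-direction overlaps.

## Gamma-renewal interference strength

Chiasmata on the four-strand bundle are modelled as a stationary renewal
process on the genetic scale with inter-arrival distances
$\Gamma(\nu, 2\nu)$ (mean 1/2 Morgan, i.e. two chiasmata per Morgan);
each chiasma resolves into the transmitted chromatid with probability 1/2
independently. $\nu = 1$ is a Poisson process (no interference), $\nu > 1$
a more regular process (positive interference), $\nu < 1$ clustering
(negative interference). The closed-form consequences used as simulation
ground truth are $r(d) = F_e(d)/2$ for the recombination fraction over $d$
Morgans and
$C(d_1, d_2) = (F_e(d_1) + F_e(d_2) - F_e(d_1+d_2))/(F_e(d_1) F_e(d_2))$
for the coincidence of adjacent intervals, where $F_e$ is the equilibrium
(residual) chiasma CDF; at $\nu = 1$ these reduce to Haldane's formula and
$C \equiv 1$.

The likelihood of observed crossover locations uses the
$2^{-k}$-weighted mixture of $k$-fold gamma convolutions for inter-event
distances, the stationary $k$-th-arrival densities for the first event,
and the corresponding censoring terms for the chromosome end and for
meioses with no event (which are retained, not dropped). The series is
truncated when the weight falls below $10^{-8}$ (27 terms). $\hat\nu$
maximises this likelihood over $[0.05, 20]$ by Brent search; standard
errors come from the numerical observed information.

Crossovers are reconstructed per progeny as sign changes of the
phase-canonicalised transmitted-allele signal between consecutive
non-missing markers (missing markers widen the bracket). Genetic marker
positions are the running sums of adjacent-interval $\hat r$ (additive
approximation, adequate at the sub-centimorgan-per-interval scale used
here; Haldane/Kosambi transforms would add little at 300-kb spacing). For
the fit, each event's position is drawn uniformly within its
flanking-marker bracket rather than placed at the midpoint: deterministic
midpoints forbid short inter-event distances and masquerade as strong
positive interference, inflating $\hat\nu$ increasingly with bracket
width. Uniform placement removes that hard-core artifact; it is
reproducible given the session seed, and `event_placement = "midpoint"`
is available for comparison.

Two genuine limitations remain. First, double crossovers inside one
marker bracket are invisible, so marker-scale $\hat\nu$ is biased upward
relative to the continuous-data fit — strongly so for clustered
($\nu < 1$) processes; per-chromosome $\hat\nu$ values from marker data
should be read as *comparative* measures between parents fitted on the
same marker grid, not as absolute interference strengths. The recovery
tests therefore check absolute accuracy on directly simulated event
positions and only the between-parent ordering on marker data. Second,
with heavy missingness the effective marker spacing grows and both the
genetic scale and the event set degrade; both parents are affected
symmetrically under the missing-at-random model simulated here.

The parents are compared with a two-sided paired *t* test on
per-chromosome $\hat\nu$; a zero-variance difference vector is reported
degenerately (|t| = ∞, p = 0 for a constant non-zero difference) with a
warning.

## The simulator and what it emulates

`simulate_population()` draws, per progeny, chromosome and parent, one
transmitted chromatid from the thinned stationary gamma-renewal process
(first chiasma from the equilibrium residual distribution by exact inverse
CDF, so no burn-in approximation), assigns linkage phases per marker
(random by default, matching an outbred parent), converts transmitted
alleles to het/hom calls relative to the informative parent, and applies
missingness uniformly at random. Optional transmission distortion and a
uniform miscall rate exist only to exercise the filters. Default
conditions mirror the target study: 257 progeny, the 19 chromosome sizes
of the reference assembly (394 Mb), tags every 300 kb with the two SNPs
400 bp apart, $\nu_f = 0.559$, $\nu_m = 0.611$, 7% missing calls (the
average observed rate; the filter tolerates up to 20%), genetic lengths
of 0.15 Morgan/Mb giving per-interval rates around 0.045, within the
0.004–0.22 range reported per interval in the target study. The physical
to genetic map is linear per chromosome; the simulator does not model
sequencing reads, locus dropout, obligate chiasma formation, or
non-uniform recombination landscapes, so recovery tests validate the
estimators under the stated model, not robustness to hotspot structure.

`heterochiasmy_chromosomes()` builds study conditions where the female's
per-interval rates exceed the male's by a fixed factor: because $r(d)$
depends on $\nu$ through $F_e$, the female map length is solved
numerically per chromosome rather than scaled linearly.

## Filters and tag selection

Markers are dropped when (in order) the parental genotypes are not one of
the two informative configurations; more than 20% of progeny calls are
missing (strict inequality); or the het:hom counts deviate from 1:1 by the
one-degree-of-freedom chi-square without continuity correction at
$p < 0.01$ (keeping ties at exactly 0.01 — the keep rule retains
non-deviating markers). At VCF import, het calls require depth ≥ 3 and
genotype quality strictly > 30, hom calls depth ≥ 5; failing or
cross-inconsistent calls become missing. Tag pairing takes the closest
opposite-type SNPs within 1 kb, each SNP used once; tag spacing is a
greedy left-to-right walk with a strict 100-kb gap (deterministic and
order-independent given sorted input); k spaced tags yield k−1 analysis
intervals per chromosome.

## Numerical and validation choices

* Chi-square p-values are asymptotic everywhere, including small counts;
  low-information rows are flagged (`low_n`, `no_test`) instead of being
  switched to exact tests. No multiple-testing correction is applied by
  default, matching the per-interval reporting convention of the target
  design; `p.adjust` can be applied downstream.
* Type-I calibration of the interference LR test is validated at
  $r_1 = r_2 = 0.2$, $n = 250$ (expected double count 10). At smaller
  rates (e.g. $r = 0.1$, $n = 250$, expected double count 2.5) the
  discreteness of the double count makes *any* $\chi^2_1$-referenced
  implementation over-reject; this is a property of the test at that
  design point, not of the implementation.
* The coincidence MLE is exact but noisy: at $n = 10{,}000$ and
  $r_1 = r_2 = 0.1$ the delta-method sampling SD of $\hat C$ is about 6%
  of $C$ at $C = 2$ and 14% at $C = 0.5$, driven by the expected double
  counts (200 and 50); the model is saturated, so no estimator does
  better. Recovery runs report the mean of $\hat C$ (unbiased to within
  Monte-Carlo error) and the fraction of replicates within ±10% of
  truth, which is intrinsically bounded by this sampling noise.
* Validation problem sizes: 1,000 random tables for oracle equivalence
  (two-point grid at $10^{-4}$; three-point via restarted Nelder–Mead on a
  smooth logit reparameterization), 5,000 null replicates per LR
  calibration, 1,000 for power, 2,000 meioses per $\nu$ recovery fit, and
  an end-to-end genome of 5 × 20 Mb chromosomes with 250 progeny and 20%
  missing calls.

## Worked example

```{r, eval = FALSE}
library(radxo)
chroms <- heterochiasmy_chromosomes(n_chrom = 5, rate_ratio = 1.3,
                                    nu_female = 0.55, nu_male = 0.9)
cfg <- sim_config(n_progeny = 250, chromosomes = chroms,
                  nu_female = 0.55, nu_male = 0.9,
                  missing_rate = 0.2, seed = 1)
sim <- simulate_population(cfg)
res <- analyze_f1(sim$dataset, mils = 0.5e6,
                  rate_test_level = "interval")
res$rate_comparison$summary
res$interference$summary
res$strength
```
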