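# radxo

Sex-specific crossover rates and crossover interference from RAD tags in
outbred F1 populations.

## The problem

Comparing female and male recombination normally requires reciprocal
backcrosses of inbred lines — impractical in highly heterozygous,
long-generation organisms such as forest trees. In an outbred F1 cross,
however, a SNP heterozygous in exactly one parent segregates 1:1 and acts
as a pseudo-testcross marker for that parent. `radxo` analyses RAD tags
that carry **two** such SNPs — one ab×aa (female-informative) and one
aa×ab (male-informative), less than 1 kb apart — so a single F1 population
yields two parallel pseudo-testcross datasets over the *same* genomic
intervals, one per parent.

The package provides, for people working on recombination landscapes and
linkage-map construction in outbred crosses:

* **Marker handling** — VCF / TSV import with depth–quality filters,
  segregation-type classification, 1:1 chi-square and missingness filters.
* **Tag selection** — pairing opposite-type SNPs into tags (< 1 kb),
  spacing tags (> 100 kb), building analysis intervals.
* **Two-point analysis** — per-interval linkage-phase inference, crossover
  rate MLEs `r̂ = (n12 + n13)/n` per parent, the likelihood-ratio test of
  rate equality (χ²₁), significant-region detection, and the genome-wide
  paired Wilcoxon signed-rank comparison.
* **Interference** — three-point coefficient-of-coincidence MLEs
  `Ĉ = n₁₁/(n r̂₁ r̂₂)` with full linkage-phase-case resolution, the
  interference LR test, and a minimum-interval-length (0.5–5 Mb) scan
  classifying negative (Ĉ > 1) and positive (Ĉ < 1) interference.
* **Interference strength** — crossover-event reconstruction per meiosis
  and a stationary gamma-renewal fit of the interference strength ν per
  chromosome and parent (ν = 1 none, ν > 1 positive, ν < 1 negative),
  with a paired t comparison between parents.
* **A meiosis simulator** — thinned stationary gamma-renewal chiasma
  model with closed-form ground truth (model-implied recombination
  fractions and CoC values), sex-specific genetic maps, linkage phases,
  missingness and segregation distortion, for validating every stage by
  parameter recovery.

## Worked example

Simulate a 5-chromosome genome in which the female recombines 1.3× faster
than the male and interferes more strongly (ν_f = 0.55 vs ν_m = 0.9,
i.e. both parents show crossover clustering), with 20% missing calls,
then run the full pipeline:

```r
library(radxo)
chroms <- heterochiasmy_chromosomes(n_chrom = 5, rate_ratio = 1.3,
                                    nu_female = 0.55, nu_male = 0.9)
cfg <- sim_config(n_progeny = 250, chromosomes = chroms,
                  nu_female = 0.55, nu_male = 0.9,
                  missing_rate = 0.2, seed = 1)
sim <- simulate_population(cfg)
res <- analyze_f1(sim$dataset, mils = 0.5e6, rate_test_level = "interval")
```

The per-chromosome rate summary shows the simulated heterochiasmy:

```
 chrom n_intervals mean_r_f mean_r_m
 Chr01          22   0.1162   0.1172
 Chr02          17   0.1556   0.1325
 Chr03          14   0.1619   0.1388
 Chr04          16   0.1535   0.1374
 Chr05          18   0.1372   0.1164
interval-paired signed-rank p: 1.42e-05
```

The female's mean rate exceeds the male's on 4 of 5 chromosomes and the
paired signed-rank test over the 87 intervals is decisive. (Interval rates
exceed the per-300-kb truth because the >20%-missing filter removes about
half the markers at this missingness, roughly doubling interval lengths.)
The interference scan at MIL = 0.5 Mb recovers the direction of the
simulated clustering — significant pairs are dominated by Ĉ > 1
(negative interference), more so in the female:

```
 parent n_pairs n_sig n_coc_gt1 n_coc_lt1 coverage
 female      65     5         4         1    0.144
   male      65     2         2         0    0.066
```

and the gamma fits order the parents correctly (marker-scale ν̂ is
upward-biased by interval censoring, so compare parents, not absolute
values — see the methods vignette):

```
 parent nu_hat
 female  1.290
   male  1.574
strength: mean nu_f=1.290 mean nu_m=1.574 paired-t p=0.001
```

A thin command-line front end over the same functions is installed at
`inst/scripts/radxo-cli.R` (subcommands `simulate`, `filter`,
`select-tags`, `corate`, `interference`, `strength`).

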