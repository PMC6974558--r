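# apiculate

Population genetics and hybrid genome profiling for apiculate yeasts
(*Hanseniaspora* and relatives), the dominant genus of grape-must
microbiota.

Closely related *Hanseniaspora* species hybridize in nature, producing
allodiploid, allotriploid and allotetraploid strains whose genomes keep
rearranging (chromosome loss, auto-diploidization, segmental
duplication, loss of heterozygosity). Characterizing such strains takes
two complementary toolkits, and this package implements both as
composable, tibble-in/tibble-out R functions:

* **MLST population genetics** — multi-locus sequence typing alignments
  with IUPAC-coded heterozygous positions; per-locus site counts and
  nucleotide diversity (Π per locus, π per kb); the Weir–Cockerham
  multilocus inbreeding coefficient F<sub>IS</sub>; selfing-rate
  estimation both from the equilibrium transform *s* = 2F<sub>IS</sub> /
  (1 + F<sub>IS</sub>) and by maximum likelihood from the multilocus
  heterozygosity profile (each individual carries a latent number *t* of
  consecutive selfing generations, P(*t*) = (1 − *s*)*s*<sup>*t*</sup>,
  and is heterozygous at locus *k* with probability
  *h*<sub>0k</sub>·2<sup>−*t*</sup>); STRUCTURE-format export.
* **Hybrid subgenome profiling** — competitive assignment of short reads
  to two parental reference genomes with removal of ambiguous reads;
  1700-nt windowed read depth normalized to the depth of one chromosome
  copy (log2 scale) and integer copy-number calls; a pileup genotyper
  plus GATK-style hard filtering (QD < 5, FS > 55, SOR > 2, MQ < 40,
  rank-sum tests < −5); bi-/tri-allelic classification with the 5%
  reference-read rule; heterozygous-SNP density in 10-kb windows with
  LOH segment detection; minor-allele balance in 2-kb windows (mode ≈
  1/2 for diploid, ≈ 1/3 for triploid subgenomes); IBS0/IBS1 pairwise
  distances and SNP PCA.
* **Flow-cytometry ploidy** — G1/G2 DNA-content peak fitting with a
  constrained two-component mixture (G2 ≈ 2×G1) and relative ploidy
  calls against a reference strain.
* **Synthetic data with ground truth** — generators for diverged
  parental genome pairs, hybrid chromosome complements with planted
  heterozygosity and LOH tracts, paired-end reads with errors, MLST
  panels under partial selfing, and G1/G2 fluorescence mixtures. Every
  analysis stage can therefore be validated against known truth.

## Worked example

Mating-system inference on a simulated panel of 200 individuals at five
loci with true selfing rate 0.8:

```r
library(apiculate)

panel <- simulate_mlst_population(200, 5, h0 = 0.5, s = 0.8, seed = 42)
selfing_estimate(panel)
#> # A tibble: 1 × 5
#>     fis s_from_fis s_from_profile s_profile_se g2_hat
#>   <dbl>      <dbl>          <dbl>        <dbl>  <dbl>
#> 1 0.708       0.83          0.807       0.0269   1.41
```

Both routes recover the truth: the equilibrium transform of the
Weir–Cockerham F<sub>IS</sub> gives 0.83 and the profile likelihood
0.81 ± 0.03 against the true 0.8; the positive identity-disequilibrium
diagnostic `g2_hat` confirms heterozygosity is correlated across loci,
the signature of selfing rather than mere low diversity.

An end-to-end allotriploid run (2 chromosome sets from parent A, 1 from
parent B, heterozygous at 5 sites/kb on the A subgenome):

```r
run <- run_pipeline(list(
  outdir = "triploid_demo", seed = 7,
  simulate = list(length = 1e5,
                  segments = data.frame(start = 0, end = 1e5,
                                        copies_a = 2, copies_b = 1),
                  het_rate_a = 5, coverage = 20)
))
res <- attr(run, "results")
attr(res$cn, "proportion")                      # "2:1"
attr(res$het_windows, "pct_heterozygosity")     # 0.491
res$flow_call
#> # A tibble: 1 × 5
#>   ploidy ploidy_integer distance_to_integer normalized_g1 flags
#>    <dbl>          <int>               <dbl>         <dbl> <chr>
#> 1   3.00              3             0.00129          1.50 ""
```

The coverage track recovers the 2:1 parental proportion diagnostic of an
allotriploid, the heterozygosity map recovers the planted ~0.5% A-subgenome
heterozygosity, and the flow-cytometry stage calls the strain triploid
against a diploid reference. Each result type has an `autoplot()` method,
and fitted objects support `tidy()` / `glance()`.

## Documentation

The methods vignette (`vignettes/hybrid-genome-analysis.Rmd`) describes
the models, the defaults and their units, what the synthetic generators
do and do not emulate, and the package's numerical choices.
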