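---
title: "Models and methods: MLST mating systems and hybrid subgenome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: MLST mating systems and hybrid subgenome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models behind `apiculate`, the
defaults and their rationale, what the synthetic-data generators emulate
(and what they deliberately do not), and the numerical choices a
maintainer would want written down. The package targets a common study
design in yeast population genomics: a panel of strains genotyped at a
handful of MLST loci, a subset of interspecific hybrids sequenced at
shallow shotgun depth against two parental reference genomes, and
flow-cytometry DNA-content measurements for ploidy.

```{r setup}
library(apiculate)
library(dplyr)
```

## MLST diversity statistics

A marker alignment holds one Sanger-sequenced locus across strains.
Heterozygous chromatogram positions are represented by the two-fold
IUPAC codes (R, Y, S, W, K, M); `encode_heterozygous_consensus()` and
`expand_biallelic()` convert between the diploid consensus and the two
pseudo-haplotypes. Phase is not identifiable from a consensus sequence,
so expansion assigns the alphabetically first base to haplotype 1 at
every ambiguous site; every statistic computed downstream is
phase-invariant, so this choice is cosmetic but makes output
deterministic.

Site counting (`site_counts()`) uses definitions chosen to be mutually
consistent: columns containing a gap or `N` in any strain are excluded
from *all* counts; a column is *heterozygous* when at least one strain
carries an ambiguity; *polymorphic* when the union of constituent
alleles across strains has two or more bases. A column variable only
within a single strain therefore counts as both — the only reading under
which heterozygous counts can never exceed polymorphic counts.
Percentages are rounded half-up to two decimals, the convention of
published diversity tables.

Nucleotide diversity Π (`nucleotide_diversity()`) is the mean pairwise
Hamming difference across all `choose(2N, 2)` pseudo-haplotype pairs —
a *per-locus* count of differences, not a per-site rate. A per-site
rescaling is exposed as `pi_per_kb = 1000 * Pi / n_total_sites`. The
implementation uses per-column allele counts, which is algebraically
identical to enumerating all pairs; the test suite asserts exact
equality against a brute-force all-pairs oracle on alignments of up to
ten strains.

## Mating-system inference

Yeasts with intra-tetrad mating or haplo-selfing show a heterozygote
deficit. Two estimators of the selfing rate are provided.

**From the inbreeding coefficient.** `fis_estimate()` implements the
Weir & Cockerham (1984) within-individual correlation *f* for a single
population: per locus and allele the variance components

$$b_u = \frac{n}{n-1}\left(\bar p_u(1-\bar p_u) - \frac{2n-1}{4n}\bar h_u\right),
\qquad c_u = \bar h_u/2,$$

are summed over alleles and loci before forming
$f = 1 - \sum c / \sum(b+c)$; individuals missing a locus drop out
locus-wise. At inbreeding equilibrium $F_{IS} = s/(2-s)$, so
`selfing_from_fis()` reports $s = 2F_{IS}/(1+F_{IS})$, clamped to zero
with a warning when $F_{IS} < 0$ (a negative selfing rate is not
interpretable), and rounded half-up to two decimals by default. The
naive $1 - H_o/H_e$ estimator is available behind
`fis_estimate(method = "ho_he")` for sensitivity checks.

**From the heterozygosity profile.** Variation in inbreeding among
individuals makes heterozygosity *correlated across loci* (identity
disequilibrium); this separates true selfing from simple low diversity.
`selfing_from_profile()` fits, by maximum likelihood, the model in which
individual *i* has undergone $t_i$ consecutive selfing generations with
$P(t) = (1-s)s^t$ for $t < t_\max$ and the full geometric tail mass
$s^{t_\max}$ lumped at $t_\max$, and is heterozygous at locus *k* with
probability $h_{0k} 2^{-t}$ independently across loci given $t$. The
tail-lumping (rather than renormalizing the truncated series) matters at
the boundary: full selfing $s = 1$ then degenerates to $t = t_\max$ and
predicts essentially zero heterozygosity, the biologically correct
limit. Defaults: $t_\max = 20$ (heterozygosity decays by $2^{-20}$,
far below detectability); optimization on the logit scale with BFGS,
multi-started over $s_0 \in \{0.1, 0.3, 0.5, 0.7, 0.9\}$ to avoid
boundary traps; the standard error comes from a central second
difference of the profile log-likelihood in *s* (step 0.01, maximizing
over $h_0$ at each evaluation). The moment diagnostic
$\hat g_2 = \mathrm{mean}_{k<l}\,[\langle H_k H_l\rangle /
(\langle H_k\rangle\langle H_l\rangle) - 1]$ is reported but never used
in the fit, so it remains an independent check. A panel with no
heterozygote anywhere returns $\hat s = 1$ with a boundary flag rather
than a spurious converged fit.

```{r selfing}
panel <- simulate_mlst_population(200, 5, h0 = 0.5, s = 0.8, seed = 42)
selfing_estimate(panel)
```

**STRUCTURE export.** `export_structure()` writes two digit rows per
individual with A, C, G, T mapped to 0–3 in alphabetical order and −9
for missing data. The digit range is fixed by the format convention for
bi-allelic nucleotide positions; the base order and missing code are
this package's documented choice and are configurable.

## Subgenome profiling of hybrids

**Read assignment.** `assign_reads()` emulates competitive mapping
against two parental references with removal of ambiguous reads. The
built-in aligner (exact k-mer seeds at three read offsets, full-length
Hamming extension, default `k = 31`, mismatch budget 10) exists so that
the whole pipeline runs without an external aligner; `read_sam_assignment()`
is the production path and applies the same uniqueness rule to
pre-computed alignments (`AS` score, `NM` fallback). "Ambiguous" means
the best score is achieved in both references — with indel-free
simulated reads, a score tie. The expected information content is
binomial: a read of length *L* overlaps no diagnostic site with
probability $(1-d)^L$, e.g. 22% at $d = 0.01$ and 0.2% at $d = 0.04$
for 150-bp reads, so the ambiguous fraction is itself a check on the
assumed divergence.

**Coverage and copy number.** `coverage_profile()` computes mean
unique-read depth in non-overlapping 1700-nt windows (the window size
standard for two-parent coverage visualization; 10-kb and 2-kb windows
are the defaults of the heterozygosity and allele-balance tracks
respectively, all overridable). Depth is normalized by the depth of one
chromosome copy — pooled unique-read depth over both subgenomes divided
by the total ploidy — and log2-transformed with a pseudo-depth of 0.25
reads (half the minimum countable) for empty windows. When total ploidy
is unknown it is estimated as the integer in 2–4 minimizing the mean
squared rounding residual of normalized window depths, and flagged.
Because ambiguous-read removal discards a few percent of reads from both
subgenomes, normalized depths sit slightly below their nominal integers;
`infer_copy_number()` therefore median-filters (width 5 windows) before
rounding, caps calls at `round(total_ploidy) + 1` (a locally duplicated
segment can exceed the genome-wide mean ploidy), and flags windows whose
smoothed depth sits persistently more than 0.2 copies from an integer —
the signature of a heterogeneous cell population rather than a clean
plateau. The parental proportion is the genome-length-weighted mean copy
number per subgenome, reduced (e.g. `2:1` for an allotriploid).

**Variant sites.** `pileup_genotype()` is a deliberately simple counting
caller for the simulated path: a site is emitted when a non-reference
allele reaches 15% of reads at depth ≥ 8. It reports GT and AD and
leaves the GATK-style annotations missing rather than fabricating them;
`read_vcf_sites()` populates them on VCF import. `hard_filter()` removes
sites with QD < 5.0, FS > 55, SOR > 2.0, MQ < 40, MQRankSum < −5.0 or
ReadPosRankSum < −5.0 — a missing annotation simply passes that check.
`classify_allelic_state()` applies the GT/AD rule for polyploid call
sets: `0/1` is bi-allelic; `1/2` is bi-allelic when under 5% of reads
support the reference and tri-allelic otherwise. Whether the 5% clause
should also gate `0/1` genotypes is genuinely ambiguous; the default
treats `0/1` as unconditionally bi-allelic, and `strict_01 = TRUE`
switches to the alternative reading.

**Heterozygosity, LOH, allele balance.** `het_density_windows()` counts
filtered bi-allelic heterozygous SNPs in 10-kb windows and reports
genome-wide heterozygosity as `100 * sites / reference length`; the
denominator is the full subgenome length (configurable), the convention
that makes values comparable across strains with different callable
fractions. `detect_loh()` emits maximal runs of at least 5 consecutive
windows with at most 1 heterozygous SNP — i.e. LOH tracts of ≥ 50 kb at
the default window, below which a gap is indistinguishable from sampling
noise at typical densities. `minor_allele_windows()` summarizes
per-site minor-allele depth fractions in 2-kb windows; the global mode
is estimated after reflecting the sample around 1/2, because the folded
fraction is bounded at 0.5 and a naive kernel mode would be biased
about 0.03 low for a diploid signal. A mode near 1/2 indicates even
allele balance, near 1/3 a triploid-like state (variant on one of three
copies).

**Between-strain distance.** `ibs_matrix()` counts, per strain pair over
jointly called sites with no missing data, the sites sharing zero
(IBS0) and exactly one (IBS1) allele identical by state; for haploid
subgenomes only IBS0 is meaningful and IBS1 is reported as `NA`. IBS0 is
not a metric, so only symmetry and count conservation are guaranteed.
`snp_pca()` centers non-major-allele dosages and eigendecomposes via
`prcomp`; variance fractions sum to one across components.

## Flow-cytometry ploidy

`detect_g1_g2()` fits a two-component normal mixture to gated event
intensities by EM, initialized from the two largest kernel-density modes
whose ratio falls in 1.7–2.3, with the G2/G1 mean ratio projected into
that band after every M-step (the biological constraint G2 = 2×G1,
relaxed ±15% for dye and instrument nonlinearity). Five seeded restarts
guard against local optima. Populations with no acceptable second mode
return a `g2_absent` flag; three or more well-separated substantial
modes (≥ 5% of the maximum density, > 15% apart) raise `multimodal`,
the signature of a mixed population of cells with different genome
contents. `call_ploidy()` scales the reference ploidy by the G1 ratio;
the estimate is invariant to multiplying all intensities by a constant,
so instrument units never matter. Input is a plain one-column event
table; binary FCS parsing is out of scope — convert upstream with any
flow toolkit.

## What the generators emulate — and what they do not

`simulate_parental_pair()` draws an i.i.d. uniform-base genome and a
partner diverged by uniform substitutions; there is no biological
divergence estimate between the two parental species involved, so the
default 2% in examples is a configurable modeling choice, not an
asserted biological truth. `simulate_hybrid_genome()` materializes
per-segment copy numbers (0–4 per parent), plants heterozygous sites at
a per-kb rate on exactly one copy of the carrying subgenome — only where
that subgenome has at least two copies, since a variant on a single copy
would be a substitution, not heterozygosity — and leaves LOH tracts
untouched. `simulate_reads()` draws Poisson fragment counts per
contiguous copy piece with normal insert lengths (400 ± 40 bp, 2×150 bp
reads) and uniform substitution errors.

Deliberately **not** emulated: indels and structural variants (the
hybrid analysis is SNP-based), quality-score error models, PCR/optical
duplicates, GC and mappability bias, repeats (genomes are i.i.d.
random, so k-mer seeds are nearly unique — real subtelomeres are
harder), multi-scaffold references (simulate one chromosome per call),
and a third parental species. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to every artifact of real Illumina data; the SAM/VCF import
paths exist precisely so real pipelines can feed the same statistics.

The MLST generator draws bi-allelic loci, which bounds the outcrossed
heterozygosity at `h0 <= 0.5` (the Hardy–Weinberg maximum); homozygote
alleles are drawn so the marginal allele frequency is preserved at every
selfing depth, which keeps the panel exactly at the equilibrium
`E[Fis] = s/(2-s)` that the estimator inverts. The flow generator fixes
the G2 mean at exactly twice G1 and resamples negative intensities.

## Problem sizes and determinism

All randomness flows from one explicit integer seed per generator call
through R's default Mersenne-Twister generator, so seeded reruns are
byte-identical (asserted for FASTA/FASTQ/BED/TSV outputs of
`run_pipeline()`). The test suite exercises the recovery properties at
the scales the methods are designed for: MLST panels of 400–500
individuals at 5 loci, 20 replicate fits for the profile-likelihood
estimator, 200-kb genomes at 30× per chromosome copy for copy-number
and LOH recovery, 60-kb genomes for allele-balance modes, and 20,000–
30,000 flow events per sample — sizes chosen so each property check
completes in minutes on a single core while keeping Monte-Carlo noise
well inside the asserted tolerances.

## Known limitations

* The built-in aligner takes the first k-mer match per seed; on highly
  repetitive references it can misplace reads that a full aligner would
  flag multi-mapping. Use the SAM import path for real data.
* The pileup caller has no base-quality model and no indel
  realignment; it is a validation tool for simulated reads, not a
  production variant caller.
* `selfing_from_profile()` assumes a stationary mating system and
  independent loci given the selfing depth; linked loci inflate
  `g2_hat` and can bias `s` upward.
* Flow fits assume debris/doublet gating happened upstream; ungated
  events typically trigger the `multimodal` flag rather than a wrong
  call, but are not modeled.
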