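# hapclean

Robust genotype error correction for low-coverage reduced-representation
sequencing (GBS / RAD-seq) data from crossing populations.

## The problem

Genotyping-by-sequencing trades read depth for sample throughput: with
0.1–3× coverage per site, a heterozygote often shows reads of only one
allele and gets undercalled as a homozygote, and many calls are missing
outright. Worse, real marker panels contain *error-prone markers*: uneven
amplification of restriction fragments skews the probability of sampling
each allele's reads (allele read bias), and reads mismapped from paralogous
loci make homozygotes look heterozygous. Error-correction models that
assume a uniform 50:50 allele read ratio at every marker are systematically
deceived by such markers.

`hapclean` corrects genotypes in mapping populations (biparental F2,
outbred F1, 8-way RIL, and custom designs) with a hidden Markov model that
estimates *marker-specific* error parameters.

## The model

For each offspring, the hidden state at marker *m* is the ordered pair of
ancestral haplotypes `h = (h1, h2)` (which founder chromosome each homolog
descends from; `K` ancestors, `K²` states). Founder genotypes
`x^f = (x_1, …, x_{N_f})` are jointly estimated with the offspring
haplotypes by maximizing

```
P(H, X^f, Y^o, Y^f) =
  Π_m l^f_m(x^f_m) P(x^f_m) ·
  Π_i [ π(h_1i) Π_m l^o_mi(h_mi | x^f_m) Π_{m≥2} P(h_mi | h_{m-1,i}) ]
```

* **Transitions** `P(h_m | h_{m-1}) = exp(Q d_m)`, a continuous-time Markov
  chain over ancestral haplotypes; `d_m = 10⁻⁶ (p_m − p_{m−1}) E^d` Morgans
  with `E^d` the expected genetic distance per megabase (default 0.04, i.e.
  1 Mb = 4 cM).
* **Emissions**: reads `y = (y_ref, y_alt)` given observable genotype
  follow binomial kernels — `(1−e_seq)^y_ref e_seq^y_alt` at a reference
  homozygote, `(1−w_m)^y_ref w_m^y_alt` at a heterozygote (mirrored for the
  alternative homozygote), where `w_m` is the marker's alternative-allele
  read probability (0.5 when unbiased). A mismapping layer lets a true
  homozygote be observable as a heterozygote with marker-specific rates
  `(e_ref, e_alt)`.
* **Decoding**: an integrated Viterbi algorithm scores founder-genotype
  combinations alongside every offspring trellis, in two rounds (forward
  and constrained reverse, merged at mid-chromosome); posterior genotype
  probabilities come from the forward–backward algorithm and calls below
  `P_call` (default 0.9) are reported missing.
* **Iterative parameter optimization (IPO)**: `w_m` and `(e_ref, e_alt)`
  are re-estimated from each round's genotype estimates and the estimation
  is repeated (default 4 cycles).

The package also ships the crossing-population simulator used to validate
the method (true haplotypes, genotypes, biased and mismapped read counts)
and the evaluation metrics (call rates, masked-call concordance,
recombination segments and double crossovers, segregation distortion).

## Worked example

Simulate a biased F2 (100 offspring, 620 markers on a 50 Mb / 2 Morgan
chromosome, 3× offspring and 5× founder coverage, 30% bias-prone markers),
then correct it:

```r
library(hapclean)
sim <- simulate_cross(scenario = "homoP2_F2", n_offspring = 100,
                      n_markers = 620, offspring_depth = 3, seed = 42)
sim$ds
#> <hc_dataset> 620 markers on 1 chromosome(s); 2 founders, 100 offspring
#>   mean read depth per cell: 3.06

set.seed(42)
fit <- run_ipo(sim$ds, mating_design("homoP2_F2"), cycles = 4)
round(call_metrics(fit$estimate$offspring_geno,
                   sim$truth$offspring_geno)$mean, 4)
#>  correct  miscall  missing accuracy
#>   0.9866   0.0021   0.0112   0.9978

mean(abs(fit$params$w - sim$truth$w)[fit$bias_informative >= 50])
#> [1] 0.025
```

98.7% of the 62,000 genotype calls are correct (99.8% of the nonmissing
ones), and the per-marker allele-read-bias estimates land within 0.025 of
the simulated truth on average. Naive read-based calls on the same data are
wrong or missing at roughly a third of cells.

For VCF input, the same pipeline is one call:

```r
correct_genotypes("reads.vcf", "corrected.vcf",
                  founders = c("P1", "P2"), scenario = "homoP2_F2",
                  cycles = 4, seed = 1)
```

The output VCF carries the called genotype (`GT`), the original allele
depths (`AD`), and the posterior probability of each call (`PC`).

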