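---
title: "The hapclean error-correction model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hapclean error-correction model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapclean)
```

# Scope and assumptions

`hapclean` estimates true genotypes along a chromosome for a mapping
population derived from `N_f ≥ 2` diploid founders, given only per-marker
allele read counts (the `AD` field of a VCF). It assumes biallelic markers
ordered along chromosomes, chromosomes independent of one another (each is
processed separately), founders either all inbred or all outbred, and
offspring that are conditionally independent given the founder genotypes.
Input genotype calls are ignored entirely: low-coverage calls are exactly
what the model is meant to replace.

# The hidden state and the joint probability

The hidden state of offspring *i* at marker *m* is the ordered pair of
ancestral haplotypes `h = (h1, h2)`. With inbred founders each founder
contributes a single ancestral haplotype (`K = N_f`); with outbred founders
each founder chromosome is its own ancestor (`K = 2 N_f`). Haplotype pairs
are kept ordered (`(1,2) ≠ (2,1)`): collapsing symmetric pairs would save
half the states but complicate indexing, and the likelihood treats them
symmetrically anyway.

Founder genotypes are phased per founder and restricted to the homozygotes
`(0,0)`/`(1,1)` when founders are inbred. A *founder combination* assigns
one phased genotype to each founder; combinations where every founder is
identical are excluded (such markers do not segregate and carry no
information about ancestry), and a discrete uniform prior is placed on the
remaining combinations at every marker. Given a combination and a haplotype
pair, the offspring genotype is fully determined — that deterministic map
is what couples the founder and offspring layers.

The joint probability maximized is the product of, per marker, the founder
emission and prior, and per offspring, the initial distribution, the
transition probabilities, and the offspring emissions. The derivation
requires nothing beyond the conditional independences stated above.

# Transition model

Between adjacent markers each of the two haplotype lineages independently
leaves its current ancestor at rate `ρ` per Morgan and jumps uniformly to
one of the other `K − 1` ancestors; simultaneous jumps of both lineages
have rate zero. The resulting `K² × K²` generator `Q` has off-diagonal
entries `ρ/(K−1)` for one-lineage changes and diagonal `−2ρ`. Transition
matrices are `exp(Q d_m)` (computed by scaling-and-squaring with Padé
approximants via `Matrix::expm`; the contract is the row-stochastic
postcondition, not the algorithm), with

`d_m = 10⁻⁶ (p_m − p_{m−1}) · E^d`

converting physical to genetic distance at a constant expected rate `E^d`
Morgans/Mb. `E^d` defaults to 0.04 (1 Mb = 4 cM), the conversion used
throughout the simulation design; it must be adjusted for genomes with a
different average recombination rate, and is the single most influential
user parameter. The initial distribution is the stationary distribution of
the chain (uniform over states for this exchangeable generator; computed
generally from the leading eigenvector of the transposed transition
matrix).

`ρ` is a per-design knob (default 1 for the biparental designs, 1.5 for
8-way RILs to reflect map expansion from the extra meioses). Exact
pedigree-specific junction rates exist in the literature; a single
interpretable switch rate was chosen instead because the decoder's
behaviour depends on the transition model only through the qualitative
scale of `exp(Q d)` over typical marker spacings, and `ρ` can be set per
design when a calibrated rate is available.

# Emission model

Read counts enter through three binomial kernels over the *observable*
genotype `x′`:

* `x′ = 0`: `(1−e_seq)^y_ref · e_seq^y_alt`
* `x′ = 1`: `(1−w_m)^y_ref · w_m^y_alt`
* `x′ = 2`: `e_seq^y_ref · (1−e_seq)^y_alt`

`e_seq` is the global sequencing error rate (default 0.0025, a typical
short-read substitution rate; supply your platform's value). `w_m` is the
marker-specific probability that a read at a heterozygote carries the
alternative allele — the allele read bias, 0.5 when unbiased.

If any of the three kernels evaluates to exactly zero (possible when
`e_seq = 0` is forced, or by floating-point underflow at extreme depth —
underflow is deliberately treated the same way), 0.005 is added to all
three before normalizing, so over-represented reads can never rule out a
genotype absolutely.

Mismapping is a separate layer: a true reference homozygote is observable
as heterozygous with probability `e_ref` (mismapped alternative reads), an
alternative homozygote with probability `e_alt`, and a true heterozygote
stays heterozygous — extra mismapped reads of either allele do not change
its observable genotype. Likelihoods of the true genotype are the kernel
triple mixed through this 3×3 matrix.

Founder emissions are per-founder products of the same machinery, with
each founder's class probabilities normalized over that founder's
admissible classes (two classes when inbred, three when outbred — the
normalization scope had to be fixed somewhere, and per-founder
normalization makes the 1% pruning threshold scale-free). Classes below
0.01 are set to exactly 0, pruning clearly unsupported founder genotypes
and, with informative founder coverage, collapsing most markers to a
single admissible combination — which is also what keeps the 8-way design
(254 combinations) tractable. If pruning removes every combination at a
marker, that marker falls back to a uniform founder emission and is
reported.

# Decoding

The integrated Viterbi recursion interleaves the two layers: per marker,
per previous founder combination, each offspring trellis is advanced with
a max over predecessor states; founder combinations are then scored by the
product over offspring of the summed trellis mass, times the founder
emission and prior, and a per-marker founder backpointer is recorded.
Backtracking from the final founder argmax recovers the founder-genotype
sequence and every offspring's haplotype path. Ties in any argmax are
broken uniformly at random from the session RNG, so runs are reproducible
under `set.seed`.

Two properties of this scheme are worth stating plainly. Given the
returned founder sequence, each offspring's haplotype path is exactly
optimal (it is a standard Viterbi conditional on that sequence; the test
suite verifies this by conditional exhaustive enumeration). The founder
sequence itself, however, is selected by per-step scores that aggregate
each offspring's trellis with a *sum* rather than a max, with greedy
backpointers — a deliberate design that measures founder support by total
offspring likelihood, is robust at low coverage, and makes the joint
optimization tractable; an exact joint maximizer would have to couple all
offspring trellises through the founder sequence and scales exponentially.
On random low-information instances the returned solution can therefore
fall marginally short of the exhaustive joint maximum (empirically ~1–4%
of tiny instances, by well under one nat); on informative data the two
coincide.

Estimation runs twice, forward and reverse (reversed marker order and
distances; the generator is symmetric, so the same transition matrices
apply). The reverse round pins the last marker's founder combination to
the forward round's estimate via a point-mass prior. The merged result
takes markers `1..floor(M/2)` from the reverse round and the rest from the
forward round: by the time the reverse round reaches the chromosome start
its founder chain has seen the entire chromosome, which stabilizes the
founder-genotype estimates there (the boundary convention — `floor`, with
the reverse round supplying the first half including the midpoint marker
at odd `M` — is fixed and covered by a test). Only marker `M` is
constrained in the reverse round. In our simulations the merge is
accuracy-neutral for offspring calls (forward and reverse single rounds
are statistically identical); its value is consistency of the founder
sequence across the chromosome.

Genotype posteriors are computed by the forward–backward algorithm
conditional on the merged founder sequence, per offspring, and the
Viterbi-implied genotype is called at each cell unless its posterior falls
below `P_call` (default 0.9; raise it for conservative downstream QTL
mapping, lower it to trade missingness for miscalls). All dynamic
programming is carried in linear space with one scaling constant per
offspring per marker — argmax-invariant, and cheaper than log-space
arithmetic in the inner loops; founder scores accumulate across offspring
in log space.

# Iterative parameter optimization

Cycle 1 runs with `w_m = 0.5` and `(e_ref, e_alt) = (0.005, 0.005)` at all
markers, i.e. the uniform-error model. Each later cycle re-estimates the
per-marker parameters from the previous cycle's called genotypes
(offspring calls after `P_call` masking; founder estimates, which carry no
posterior, are always used — founders are included in both the bias and
mismap updates) and re-runs the estimation. Four cycles are the default;
there is no convergence test, matching the fixed-cycle design.

The bias update counts reads per allele copy: with `r^x(g)` the summed
reads of allele `x` over samples of estimated genotype `g`, and copy
counts of 2 per homozygote and 1 per heterozygote,

`E^ref = (r^ref(0)+r^ref(1)) / (2 n_0 + n_1)`,
`E^alt = (r^alt(2)+r^alt(1)) / (2 n_2 + n_1)`,
`ŵ = E^alt / (E^ref + E^alt)`.

`E^ref` is the expected number of reference reads contributed by one
reference allele copy; under the generative model below `ŵ` is exactly
`w`. Copy counting (rather than excluding heterozygotes, or counting them
as two copies of each allele) is what keeps both denominators defined at
every marker and the estimator unbiased. Estimates are clamped to
`[0.02, 0.98]`: a marker at `ŵ = 1` would make heterozygotes unobservable
in every later cycle, an absorbing mistake no subsequent data could undo.
Markers with no informative copies (or no reads) carry the previous value
forward.

The mismap update counts cells whose reads alone give a normalized
heterozygote probability above 0.99 while the HMM called a homozygote —
the signature of mismapped reads overruled by linkage — as a fraction of
cells called that homozygote. It uses the current cycle's `w_m`, and
carries values forward at empty denominators.

# The simulator

`simulate_cross()` generates the three standard designs on one chromosome
(defaults: 620 evenly spaced markers, 50 Mb, 2 Morgans, founders at 5×).
Crossovers per gamete are Poisson with mean the map length, placed
uniformly on the genetic map — no interference, consistent with the
Poisson double-crossover yardstick used in evaluation. Pedigrees: F2 is
one selfing of the F1; the outbred F1 is a direct cross of two
heterozygous founders (every marker segregating among the four founder
chromosomes); 8-way RILs go through three rounds of pairwise funnel
crossing and then `ril_selfing_gens` selfing generations (default 5, i.e.
F6), each offspring an independent descent.

Reads are emitted **per allele copy**: at a marker with bias `w`, each
reference copy yields `Poisson(depth · (1−w))` reference reads and each
alternative copy `Poisson(depth · w)` alternative reads. An unbiased
marker therefore gives `Poisson(depth)` total reads at every genotype, and
the alternative-read fraction at a heterozygote is exactly `w`. This is
the natural model of allele-specific amplification efficiency — the
mechanism by which restriction-fragment GC content and length skew GBS
data — and it is what makes the bias identifiable: the disfavored allele's
homozygotes are also under-covered, so homozygote coverage carries bias
signal and the copy-counting estimator above is consistent. A model that
biased only the heterozygote read split while leaving homozygote coverage
untouched would leave the bias only partially identifiable from an F2
(the estimator would shrink halfway to 0.5). Mismapping then flips each
read to the opposite allele with the marker's rate. Under the default
`nonzero` mode every founder cell gets one guaranteed true-allele read
plus `Poisson(max(rate−1, 0))` extras, mimicking pipelines that discard
markers unobserved in a founder; `nonzero = FALSE` (the harder
"allowzero" condition) skips the guarantee.

Error-prone markers default to a 30% bias-prone fraction with true
`w ~ Beta(0.3, 0.3)` (heavy mass near 0 and 1, emulating severely skewed
empirical panels) and a 10% mismap-prone fraction with rates uniform on
`[0.05, 0.3]`. These knobs are the study conditions for the package's own
validation; all are exposed so an empirical bias profile can be matched.

What the simulator does *not* emulate: linked clusters of error-prone
markers (bias and mismap markers are placed independently at random),
crossover interference, segregation distortion from selection, marker
density variation, and sequence-level artifacts (it produces counts, not
reads). Passing tests on simulated data therefore demonstrate correctness
of the estimator under the stated generative model, not immunity to every
failure mode of real libraries — which is why the masked-concordance
evaluator exists for real data.

# Evaluation metrics

Against simulated truth: per-offspring correct/miscall/missing rates
(partitioning to 1) and accuracy over nonmissing calls. Without truth:
mask reliable calls (more than 6 reads, at markers with under 20% missing
and over 40% minor allele frequency, both computed from naive read-based
calls — genotype from which alleles were seen, missing at zero reads),
re-estimate, and report the fraction of masked cells reproduced. Estimator-
missing masked cells count as discordant and are also reported separately.
Recombination breakpoints are midpoints between adjacent nonmissing calls
that switch genotype; segments (terminal ones included) are tabulated in
0–1 and 1–2 Mb bins, and heterozygous segments flanked by the same
homozygote on both sides are counted as double crossovers — under the
Poisson model a 1-Mb window at 4 cM/Mb double-recombines with probability
`1 − e^{−d}(1+d) ≈ 0.08%`, so an excess of such segments is a miscall
diagnostic, not biology. Segregation distortion per marker is the χ²
against 1:2:1 over nonmissing calls divided by their number, summed per
chromosome.

# Numerical and design choices

* Quantile for the over-represented-read filter: type-7 (linear
  interpolation) over each sample's per-allele counts including zeros;
  the estimator type is an argument. A call exceeding either allele's
  threshold loses **both** counts — a spike of one allele discredits the
  whole call, since mismapped fragments carry both alleles of their
  source locus.
* Missing `AD` is read as `(0, 0)`: zero reads *is* the model's missing
  state; no separate missing code exists internally.
* Multiallelic records are dropped, not split, with a message reporting
  the count.
* Tie-breaking everywhere is uniform at random from the session RNG;
  `correct_genotypes()` seeds it once per run and records the seed.
* Degenerate inputs: an all-zero dataset decodes to an arbitrary
  admissible solution whose calls are all masked by `P_call`; a
  single-marker chromosome reduces to prior-weighted emissions; an
  all-pruned founder marker falls back to a uniform founder emission.

# Problem sizes used for validation

The shipped tests validate the estimator against exhaustive enumeration on
instances of up to 3 markers and 2 offspring (where enumeration is exact),
and run the full design — 620 markers, 100 offspring, 3–20× depth, 4 IPO
cycles, 10 seeds for the paired comparisons — for the closed-loop
accuracy, bias-recovery, and IPO-benefit checks. A single 4-cycle run at
that scale takes a few seconds on one CPU; the complete suite runs in a
few minutes.

# Known limitations

* Founder-sequence selection is heuristic (see *Decoding*); it is exact in
  the regimes that matter (informative founder reads) but not guaranteed
  optimal on arbitrarily diffuse data.
* One `E^d` for the whole genome: strong local recombination-rate
  variation (centromeres, hotspots) misscales `d_m` locally.
* Founders must be all inbred or all outbred; no X chromosome, no
  polyploidy, no pedigree-specific transition rates.
* IPO estimates marker parameters from the population itself; designs with
  very few offspring give noisy `ŵ` (the carry-forward and clamping rules
  bound, but do not remove, that noise).
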