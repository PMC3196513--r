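---
title: "Cumulative cell divisions as a timescale for serial-passage evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative cell divisions as a timescale for serial-passage evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccdtime)
```

## The timescale

Adaptive laboratory evolution (ALE) experiments propagate a microbial
population through daily serial passages — grow a flask, transfer a small
sample into fresh medium, repeat — until the selected phenotype (here,
growth rate) stops improving. The natural clock for such an experiment is
not wall time or even generations: the chance that a beneficial mutation
appears is proportional to the number of chromosome replications, i.e. to
the number of *cell divisions*. Two experiments that pass different cell
numbers through their bottlenecks accumulate mutational opportunity at very
different rates per generation.

`ccdtime` therefore scores an evolution by its **cumulative cell divisions
(CCD)**. Under three assumptions — binary fission, negligible death, and
exponential growth between passages — every division adds exactly one cell
to the census, so a flask inoculated with $N_{0,i}$ cells and harvested at
$N_i$ cells underwent

$$ d_i = N_i - N_{0,i} = N_{0,i}\,(2^{n_i} - 1), \qquad
   n_i = \log_2 (N_i / N_{0,i}) $$

divisions and $n_i$ generations, and the whole experiment of $m$ flasks
underwent $\mathrm{CCD} = \sum_{i=1}^m N_{0,i}(2^{n_i}-1)$. The two forms
are algebraically identical; the package computes both and tests their
agreement to $10^{-12}$ relative tolerance. Cell counts come from OD600
readings through a calibrated linear constant: 7.87e10 cells L⁻¹ OD⁻¹ for
ordinary cultures and 2.32e10 for cultures continuously exposed to the
mutagen NTG (N-methyl-N′-nitro-N-nitrosoguanidine changes cell morphology,
so the OD-per-cell calibration differs). The mutagen flag of a series
selects the constant; an explicit `final_cells` column always takes
precedence over conversion.

```{r ccd-example}
glycerol <- evolution_series(n0 = rep(8.5e4, 35), final_od = rep(0.71, 35),
                             condition = "glycerol")
ccd_of_series(glycerol)
```

A uniform 35-flask series at these glycerol-like settings gives ~595
generations and a CCD of ~3.9e11 — the scale typical of short-term ALE
endpoints.

## Growth rates and stabilization

Growth rate is the OLS slope of $\ln(\mathrm{OD}_{600})$ against time in
hours, restricted to the exponential window $0.05 < \mathrm{OD} < 0.3$
(open interval; out-of-window points are excluded, not clipped). With at
least three in-window points the fit is exact on noiseless exponential data
and recovers a 0.64 h⁻¹ rate within ±0.02 under ln-OD noise of σ = 0.01.

Experimenters end an ALE when the growth rate shows "no significant change"
over roughly the previous ten flasks. That phrase is not a test, so
`detect_stabilization()` makes it one, with two knobs: a trailing window
(default 10 flasks) and a relative tolerance (default 0.05). The series is
stabilized at the earliest flask where (i) the window's relative
growth-rate range $(\max - \min)/\mathrm{mean}$ is at most the tolerance
and (ii) the fitted drift across the window does not exceed the tolerance
times the mean (so a slow steady ramp that stays inside the range band
still does not count as stable). Condition-level summaries
(`summarize_condition()`) pool, per replicate, the endpoint and previous
two recorded growth rates — recorded means non-missing; gaps are skipped,
never interpolated — and average generations and CCD up to each replicate's
stabilization flask.

## The evolution simulator

`simulate_evolution()` is both the package's synthetic-data generator and a
mechanistic model of mutation supply on the CCD clock. A population is a
set of lineages (genotype, growth rate, cell count) cycled through
grow → mutate → record → bottleneck:

* **Growth** is deterministic exponential: the flask is harvested at the
  time $T$ solving $\sum_j n_j e^{r_j T} = N$, with the per-flask target
  $N$ drawn from a final-OD interval (default 0.6–0.8, i.e. ~1.1e10 cells
  in 200 ml). At censuses of $10^9$–$10^{10}$ cells, demographic growth
  noise is negligible; stochasticity enters through mutation and the
  bottleneck. Fractional counts are resolved by largest-remainder rounding
  so the census is exact.
* **Mutation** supply is division-proportional: each lineage contributes
  $\mathrm{Binomial}(d_j, \mu \cdot k)$ new beneficial mutants, where
  $d_j$ is its division count, $\mu$ the per-division beneficial-mutation
  probability and $k$ the mutagen multiplier (1 without NTG, 10 with).
  Each mutant is one daughter cell of an already-counted division, so the
  census and the division ledger stay exact. Effects are additive
  growth-rate gains drawn from an exponential distribution, truncated at a
  hard cap `gr_cap` representing the stable phenotype.
* **Bottleneck**: a multinomial sample of the transfer inoculum
  (log-uniform over 2.5e4–1.2e6 cells) over lineage counts.

The run stops when the recorded (population-mean) growth rates satisfy the
stabilization rule, or at `max_flasks` (default 60). The rule is armed only
once the mean growth rate has improved over the ancestor by more than the
tolerance: a literal reading would end every experiment at flask 10, before
any adaptation, which no experimenter would accept. When the configured
supply is zero no adaptation is possible and the rule applies as stated.

Emitted passage records carry exact cell counts alongside OD600 readings,
so `ccd_of_series()` of the emitted series equals the internally counted
divisions *exactly*, every seed — the conservation law the test suite and
acceptance script both check.

### Performance and an exact aggregation

A mutant is seeded as a single cell among ~$10^{10}$, so its survival
through the next bottleneck is ~$10^{-5}$ to $10^{-4}$. Materializing every
one of the $10^5$–$10^6$ mutants per flask as a lineage is wasteful, so the
simulator carries the freshly seeded mutants through their first bottleneck
as one aggregated pool: the pool survives as
$\mathrm{Binomial}(\mathrm{transfer}, M/N)$ cells, which are then assigned
to individual mutants (and thence to parent lineages, by their supply
shares) uniformly at random, with coalescence. This two-stage sample is
distribution-identical to the full multinomial over all single-cell
lineages — a property the test suite checks at small scale against the
explicit route — and effect sizes are drawn only for survivors, which
leaves every drawn distribution unchanged. The mutation history therefore
lists mutations that outlived their first bottleneck; the total supply is
reported alongside.

### Calibration of the defaults

The passaging constants (0.2 L, 7.87e10 cells L⁻¹ OD⁻¹, final OD ~0.7,
transfers of 2.5e4–1.2e6 cells, ~14–19 generations per flask) are the
experimental settings of a glycerol evolution. Two parameters are genuinely
open and were fixed once, by calibration, then frozen:

* `mu_per_division = 3e-5`. This is an *effective* supply rate, not a
  literal genomic beneficial-mutation rate: seeding mutants as single cells
  at passage time omits the within-flask amplification a real mutant
  enjoys by arising mid-growth (the Luria–Delbrück jackpot), so the rate
  folds that amplification in. It was chosen so that the no-mutagen
  trajectory climbs quasi-continuously to the cap — as real growth-rate
  trajectories do — rather than in rare widely-spaced jumps whose quiet
  gaps would trigger the ten-flask plateau rule at an unadapted growth
  rate. At much lower supply the model stops early and low; that behaviour
  is an artifact of end-of-flask seeding, not of the biology being
  modelled.
* `effect_size_mean = 0.03` h⁻¹, with `gr_initial = 0.25` and
  `gr_cap = 0.64` h⁻¹ (ancestral and evolved glycerol growth rates). A
  climb of ~0.4 h⁻¹ in exponential steps of mean 0.03 takes enough
  establishments that the no-mutagen condition stabilizes at roughly 25–35
  flasks — the observed timescale of ~595 generations at ~17 per flask.

With these defaults a tenfold mutagen multiplier reaches stability in
substantially fewer cumulative divisions (median ratio ~0.8 over 20+20
seeds, Mann–Whitney p « 0.01), the qualitative acceleration that motivates
continuous low-level mutagenesis. The ratio is milder than the real
experiments' because both simulated arms share identical passaging
constants (the real mutagen-exposed cultures ran at a different OD-to-cell
calibration and flask census) and because the ten-flask confirmation
window adds a fixed CCD floor to both arms.

### What the generator does not emulate

Within-flask mutant amplification (above); deleterious and neutral
passengers' effect on fitness (neutral supply can be tracked as counts
only); clonal interference beyond what lineage competition produces;
diauxie, substrate weaning, stationary-phase physiology, and death. Passing
tests on this generator show the calculus, the stopping rule and the
supply-vs-divisions bookkeeping are correct; they do not validate any
biological rate constant.

## Resequencing: profile-based SNP calling

The variant-calling module reproduces an early-Illumina in-house pipeline
for 36-nt single-end reads:

1. **Curation** drops every read containing an ambiguous base mark — the
   period of the era's base caller, and its modern equivalent 'N'.
2. **Alignment** is ungapped, both strands, with an iteratively increasing
   mismatch cap (0 through 5). A read is placed only at a unique
   best-scoring position; ties leave it unaligned at every cap (the tie
   persists as the cap rises), so the iteration at which a read places
   equals the smallest cap admitting its best placement. The engine is a
   compiled exhaustive Hamming scan with an exact-match fast path and
   early abandoning — by construction the same semantics as a brute-force
   scan, which the tests verify against an independent
   `Biostrings::neditStartingAt` oracle on hundreds of random instances.
   Gapped placement, base qualities and paired ends are out of scope.
3. **Profile**: aligned read bases (minus-strand reads reverse-complemented
   into reference orientation) are tallied per reference position into a
   4 × L count matrix — a pileup without qualities.
4. **Calling**: at each position, let $v$ be the largest non-reference
   count and $r$ the reference count; the position is polymorphic iff
   $v > 2r$ (strictly) and $v \ge$ `min_variant_count` (default 1: the
   literal threshold rule, which therefore calls a lone variant read over
   zero reference reads — raise the floor for noisy data). A tie between
   two non-reference bases yields no call and an ambiguity flag. No
   multiple-testing machinery: the rule is a hard threshold, not a test.

False-negative rates are estimated by spiking a known, non-overlapping set
of mutations (default 1,000; equal thirds SNPs, single-base insertions,
deletions) into a copy of the reference, re-sequencing the *unmutated*
genome in silico, and mapping against the mutated copy
(`fn_rate_analysis()`). Detection is scored per type by whether a call
falls inside the mutation's footprint on the mutated reference (expandable
by `match_window`). The caller is SNP-resolution, so indels are detected
only indirectly through flanking mismatch pile-ups — the per-type detection
table makes that limitation measurable rather than hidden. On uniquely
mappable sites (`mappable_positions()`, an exhaustive both-strand window
census) spiked SNPs are fully recovered at 30× error-free coverage, and
error-free reads from the unmutated reference produce zero calls.

Internally the package uses 1-based closed coordinates throughout (the R
and Bioconductor convention); emitted VCFs are 1-based as the format
requires.

## Mutation classification and overlaps

`classify_mutation()` places a SNP as intergenic, synonymous,
nonsynonymous, or in an unknown-function gene (genes annotated only as
conserved/predicted proteins, tallied separately), translating the
containing codon strand-aware. Translation uses the standard genetic code,
which coincides with the bacterial/archaeal code (table 11) for every
internal codon; start-codon special cases are deliberately ignored for
substitution classification. `overlap_partition()` computes the exact
subset-membership partition of mutation sets across strains, keyed by
position and alternate allele (nucleotide level; gene-level keys can be
derived from the annotation). `mutations_per_division()` is the endpoint
mutation count divided by the CCD — a descriptive supply statistic on the
division clock, *not* a Luria–Delbrück fluctuation-test estimator.

## Numerical and design notes

* Generations are real-valued; rounding happens only at reporting time.
* `grow_flask` solves its census equation by bracketed root-finding to
  1e-12; degenerate inputs (no growth, shrinking cultures, empty windows)
  raise informative errors rather than returning artifacts.
* Binomial mutant draws switch to the Poisson limit when a division count
  exceeds the 32-bit integer range; in the simulated regime
  ($dp \ll \sqrt d$) the two are indistinguishable.
* All randomness flows from R's global RNG; entry points
  (`sim_config()`, `fn_rate_analysis()`, `run_pipeline()`) take explicit
  seeds, and a seed plus a config reproduces a simulation bit for bit.
* Problem sizes in the shipped tests and acceptance script — 20 kb genomes
  at 30× coverage, 60-mutation spikes, 200 aligner-oracle instances, 20+20
  simulation seeds — were chosen as the smallest instances at which each
  property is sharply testable; all scale up linearly if larger runs are
  wanted.

## Limitations

The CCD calculus trusts the OD-to-cell calibration; errors in the constant
scale every division count linearly. The stabilization rule is a
deterministic stand-in for an experimenter's judgement and both its knobs
matter near the boundary. The simulator's effective supply rate is not
comparable to genomic mutation rates. The aligner is deliberately minimal
(ungapped, unique-best, mismatch-capped) — it models a specific historical
pipeline, not a modern aligner — and the caller has no coverage floor by
default, no base-quality model, and no indel resolution.
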