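---
title: "Profiling the mechanical properties of phage genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the mechanical properties of phage genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagemech)
```

`phagemech` turns a pair of genome sequences into a set of mechanical
read-outs — dinucleotide composition and spacing, predicted intrinsic
cyclizability, pentamer-model DNA shape — and the statistics needed to
compare them. This vignette explains each model, the conventions and
tunable parameters, what the synthetic-data generator does and does not
emulate, and the design decisions taken where more than one reasonable
convention exists.

## Dinucleotide statistics

Dinucleotides are counted with overlap over all `L − 1` adjacent
positions of the given (forward) strand; `AAA` contributes two `AA`.
Pairs that include an ambiguous base (`N`) are skipped rather than
counted as zero, so ambiguity never deflates a frequency silently.

Two denominators coexist deliberately:

- `frequency = count / L` (the genome length). This is the frequency
  convention used for the per-genome vectors and the 16 × 16
  differential matrix.
- `site_probability = count / (L − 1)` (the number of dinucleotide
  sites). This is the probability that a uniformly chosen site carries
  the dinucleotide, and it is the quantity whose square is the correct
  i.i.d. expectation in the PDDF. Using `L` there would bias the
  expectation by a factor `((L−1)/L)²` — negligible at genome scale but
  wrong in principle and visible at test scale.

Both columns are carried in the output so neither convention is
implicit.

The differential matrix crosses every frequency of genome A with every
frequency of genome B: `D[i, j] = f_A[i] − f_B[j]`, 256 values. With an
AT-enriched genome in the rows, rows for `AA`, `AT`, `TA`, `TT` are
positive — the red rows of the conventional heatmap. The opposite sign
convention is available as `orientation = "col_minus_row"` because
written descriptions of such matrices are often ambiguous about which
genome is subtracted from which; the default is the row-minus-column
form just described.

## Pairwise distance distribution function (PDDF)

For a dinucleotide `d`, build the 0/1 indicator track `b` over the
`M = L − 1` sites and, for each separation `s = 1..max_lag` (default
100 sites), compute

- observed: `O_d(s) = Σ_{i≤M−s} b_i b_{i+s} / (M − s)`,
- expected under an i.i.d. sequence: `p_d²` with `p_d = count_d / M`,
- ratio: `R_d(s) = O_d(s) / p_d²`.

A ratio of 1 is the random baseline; sustained peaks at multiples of a
period mean the dinucleotide recurs with that spacing. Two edge cases
are reported as computed rather than patched: at `s = 1` co-occurrence
is structurally impossible for `XY` with `X ≠ Y` (the ratio is 0) and
inflated for `XX` (two occurrences one step apart share a base), so the
default periodicity scan window starts at lag 2. When `p_d = 0` the
ratio is undefined and is reported as `NA`, never 0. The random
baseline is the analytic product expectation, not a shuffled-genome
null: it is exact for the i.i.d. model being tested against and keeps
the profile deterministic. (A shuffle null could be layered on top by
profiling a shuffled copy, but is not built in.)

### Periodicity scan

The dominant period of a ratio series is estimated by projecting the
mean-detrended series onto integer pulse trains: for each candidate
period `p` in the lag window, the comb power is

```
power(p) = ( Σ_{k : kp ≤ max_lag} x_{kp} )² / #{k : kp ≤ max_lag}
```

with `x` the detrended ratio. A sinusoidal periodogram was considered
and rejected: a recurring dinucleotide produces a pulse train whose
power is spread evenly over all in-window harmonics, and for long
periods (say 38 sites in a 100-site window, two harmonics) sinusoidal
leakage makes the immediate neighbours of the true period nearly
indistinguishable from it, so sampling noise can shift the argmax by
one. The comb projection concentrates the full signal at the
fundamental — sub-periods collect the same spikes but dilute them over
more comb teeth, super-periods miss spikes — and the `1/#teeth`
normalization keeps the noise floor comparable across periods, so the
plain argmax is the period estimate.

Prominence is the maximum comb power divided by the median over all
candidate periods, and a series is flagged `periodic` when prominence
is at least 3 (the default threshold). The flag is intentionally
liberal — the extreme-to-median ratio of ~99 noise powers regularly
exceeds 3 — and is meant as a screen for visual follow-up with
`autoplot()`, not as a calibrated test. A constant ratio series has
zero power everywhere and reports `dominant_period = NA` with
prominence 1.

## Intrinsic cyclizability

Experimental cyclizability of a 50-bp sequence is the natural log of
the ratio of its abundance in a looped population to a control
population; intrinsic cyclizability is the mean over measurement
variants and serves as a bendability proxy. `phagemech` predicts a
per-window score under a linear sequence model:

```
score(window) = intercept + Σ_{site = 1..49} w(dinucleotide at site)
```

optionally with position-specific weights (a 16 × 49 matrix). The model
is loaded from a YAML file with a recorded `provenance` field, so
externally trained coefficient sets plug in directly.

The shipped `default_cyc_model()` (`"at-flex-1"`) is a placeholder, not
a trained model: +0.02 for `AA`, `AT`, `TA`, `TT`, −0.02 for `CC`,
`CG`, `GC`, `GG`, 0 for mixed steps, intercept −0.1. It encodes only
the mechanistic direction that A/T-only steps bend more readily than
G/C-only steps, which is what the package's directional analyses need.
Its absolute scores are on the right (log-ratio) scale but are not
calibrated against loop-seq data, so published absolute means or maxima
cannot be reproduced with it; treat them as reference values contingent
on the original coefficients.

### The window grid

Windows are 50 bp wide and start every 7 bp from position 1 of a linear
genome, giving `floor((L − 50)/7) + 1` windows and no wraparound. The
grid is load-bearing: written methods that mention both "every 7th base
pair" and "a seven-base-pair overlap" are internally inconsistent, and
only the 7-bp *stride* reading reproduces the degrees of freedom of the
published two-genome ANOVA (23,605 + 21,594 windows for 165,282 and
151,205 bp; total df 45,198). The package therefore fixes stride
semantics as "distance between successive window starts".

Windows overlapping an `N` are scored `NA`, excluded from summaries,
and counted in `n_undefined` — zeros would contaminate the means the
comparison rests on.

## DNA shape

Each base position `i` (for `i = 3..L−2`) is assigned the minor groove
width and propeller twist of the pentamer centered on it; each pentamer
also contributes roll and helical twist values to its two central base
steps. An interior step is covered by two pentamers and receives their
average; the first and last covered steps have a single covering
pentamer and take its value directly. The standard pentamer-model end
rule leaves `L − 4` defined per-base values and `L − 3` per-step
values.

Two conventions are fixed and recorded because the alternatives are
equally defensible:

- **Step-to-base alignment.** Per-step tracks (roll, helical twist)
  are reported at the base position of the step's 5′ end, so all four
  tracks share one coordinate system and the correlation matrix is
  computed over jointly defined positions.
- **No reverse-complement symmetrization.** The table is used as
  given; published tables already encode their strand convention.

Zero-variance tracks produce a flagged `NA` correlation, never a silent
number, and pentamers overlapping `N` leave their positions undefined.

The built-in `synthetic_pentamer_table()` is a deterministic rule-based
stand-in (A/T content narrows the minor groove and deepens propeller
twist, central-step A/T character drives roll and helical twist, plus a
smooth pentamer-dependent term for within-class variation). Its ranges
are physically plausible, but it is synthetic: analyses meant to
reproduce published shape values must load the published query table
with `load_pentamer_table()`.

## Comparative statistics

- **One-way ANOVA** uses the textbook decomposition; `p` comes from the
  upper tail of the F distribution and `f_critical()` from its
  upper-alpha quantile (default `alpha = 0.05`). `anova_from_sums()`
  rebuilds the full table from printed sums of squares and degrees of
  freedom alone, which is how a published ANOVA can be checked without
  raw data.
- **Mann–Whitney U** is two-sided. `U` counts cross-pairs won by the
  first sample; the exact null distribution (by enumeration) is used
  when `n1·n2 ≤ 400` with no ties, otherwise a normal approximation
  with tie correction and a 0.5 continuity correction. At genome scale
  (tens of thousands of windows) only the approximation is feasible;
  exactness exists to make small-scale behaviour verifiable against
  brute-force enumeration.
- **Boxplot summaries** use quartiles by linear interpolation of order
  statistics and Tukey 1.5 × IQR whiskers, with values beyond the
  whiskers listed as outliers. The quartile method is fixed and stated
  because whisker-adjacent results depend on it.
- No multiple-testing adjustment is applied across the four shape
  features; the four tests are reported as-is.

## The synthetic-genome generator

`generate_iid()` draws bases independently with
`P(G) = P(C) = gc_target/2`; `generate_markov()` simulates a
first-order chain started from the stationary distribution of its
transition matrix, giving controllable dinucleotide bias;
`plant_periodic_motif()` overwrites (never inserts) a dinucleotide at a
fixed period so genome length and the window grid are preserved.
`synthetic_study_pair()` bundles the study conditions: two linear
genomes of 165,282 and 151,205 bp with GC targets 35.37% and 42.30%,
matching the published genome sizes and compositions. All generation is
seeded and byte-reproducible; the seed is the single RNG entry point.

What the generator emulates: genome length, GC content, first-order
dinucleotide bias, planted spacing structure. What it does not: coding
structure, repeats, GC skew, k-mer structure above order 2, or the
correlated mosaic of real phage genomes. Passing tests on synthetic
genomes therefore validate the *machinery* — counting, normalization,
grids, statistics — and directional behaviour under a known model; they
do not certify published values that depend on the real sequences, the
published pentamer table, or trained cyclizability coefficients.

## Numerical and degenerate-input choices

- All reported coordinates are 1-based inclusive; tracks written by
  `write_tracks()` mark undefined positions with the literal `NA`.
- Undefined values propagate as `NA` end to end; no section of a
  report renders `NaN` as a number.
- `U` is mapped to `T` on FASTA input; characters outside
  `A/C/G/T/N/U` are rejected with a named error, as are duplicate
  record identifiers and empty files.
- A reducible transition matrix (no unique stationary distribution) is
  an error, not a silent fallback.
- The exact Mann–Whitney path refuses ties instead of degrading
  silently; `mode = "auto"` handles the switch.
- Ratio denominators are guarded: `ratio_of_mean_magnitudes()` requires
  a nonzero first mean, PDDF ratios are `NA` when `p_d = 0`.

## Problem sizes used by the test suite

The package's property tests run at sizes chosen to make the
statistical assertions sharp while keeping the default suite fast:
PDDF flatness and the directional cyclizability contrast use 100-kb
i.i.d. genomes, planted-period recovery uses a 10-kb clean fixture
(period 10) and a 150-kb noisy background (period 38), brute-force
oracle comparisons use sequences of a few hundred bases, and the
Mann–Whitney type-I-error check uses 1000 replicates at n = 30 per
group. The full suite completes in well under a minute.

## Known limitations

- The shipped cyclizability model and pentamer table are documented
  synthetic stand-ins; absolute published values require the original
  external resources.
- Only the forward strand is analysed; no reverse-complement merging
  of dinucleotide or shape statistics.
- The PDDF baseline is analytic i.i.d., not a shuffle null.
- The periodicity flag is a liberal screen, not a calibrated
  significance test.
- No k-mers above order 2, no ORF/codon awareness, no circular
  topology.
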