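---
title: "Methods: quality evaluation of degraded hair-shaft DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality evaluation of degraded hair-shaft DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shaftqc)
```

## The problem

Rootless hair shafts, historical skins and other non-invasively collected
materials carry small amounts of highly fragmented nuclear DNA mixed with
microbial and environmental DNA. After trimming and alignment to the
species' reference genome, three read-level quantities summarise how
usable such a library is:

* $R_m$, the **mapping rate**: mapped reads divided by total cleaned
  reads. Operationally this is the endogenous-DNA proportion — exogenous
  molecules mostly fail to map.
* $R_{m0}$, the **multi-mapping ratio**: multi-mapped reads divided by
  all mapped reads. Very short fragments place ambiguously in repetitive
  genome regions, so $R_{m0}$ tracks fragmentation-driven loss of
  mapping specificity. It is undefined when nothing maps.
* $A_L$, the **mean read length** after trimming: a direct proxy for
  fragmentation degree.

Degraded DNA additionally accumulates post-mortem cytosine deamination:
C→U lesions concentrated at fragment ends, read as C→T at the molecule's
5′ end and G→A at its 3′ end under the common double-stranded library
chemistry, with per-position rates decaying from the terminus inward.
The terminal substitution profile and its summary statistics ($N_{db}$,
$R_{dm}$, and the between-sample CV) measure how far that damage has
progressed.

## Metric definitions and conventions

All denominators use **primary** alignment records (secondary and
supplementary records are parsed but flagged out). Duplicates are
*counted* by default because the upstream workflow this package mirrors
marks none; `count_duplicates = FALSE` switches them off everywhere at
once.

**Multi-mapped** is defined as *mapped with MAPQ 0*, the convention used
by BWA-backtrack for reads with repetitive placements. Libraries whose
aligner sets `XT:A:R` instead can switch via `multi_def = "xt_r"`. The
definition matters: $R_{m0}$ has no standard operational definition, and
the two conventions can disagree on other aligners' output.

**$A_L$ scope** defaults to all cleaned reads (mapped + unmapped),
because mean fragment length is a property of the extract, not of the
mappable subset; `a_l_scope = "mapped"` restricts it.

### Read-size stratification

`bin_by_read_size()` partitions reads into `[k·step, (k+1)·step)` bins
(default step 10 bp) anchored at multiples of the step, so bin edges are
sample-independent and deterministic. Each bin is represented by its
midpoint. Bins with fewer than `min_reads` (default 100) reads are still
reported but excluded from the trend fit — near-empty tail bins otherwise
dominate the regression through leverage. `fit_size_trend()` is an
unweighted OLS of the per-bin metric on the midpoint over the pooled
(sample × bin) points, reporting slope, $R^2$ and the two-sided t-test
p-value on the slope. Binning is exhaustive rather than random
subsampling: it is deterministic and uses every read.

A caveat worth knowing: regressing on bin *midpoints* is exactly
unbiased for the slope only when the within-bin mean length sits at a
constant offset from the bin edge in every bin (true for memoryless
length laws, approximately true for smooth unimodal ones). The
acceptance test for slope recovery uses a geometric fragment law for
precisely this reason.

## Damage profiling

`reconstruct_pairwise()` recovers the reference base under every aligned
column by expanding the MD tag against the CIGAR (or slicing a supplied
reference). Insertions contribute no reference base, deletions no read
base; soft-clipped bases are skipped but counted. Both base vectors of
reverse-strand records are reverse-complemented so every downstream
position is counted in the original molecule's 5′→3′ frame — this is
what makes the C→T/G→A asymmetry interpretable.

`compute_damage_profile()` counts, at each position $i = 1..w$ from the
chosen end (window $w$ = 25 bp by default), molecules whose reference
base is the substitution source (C for C→T, G for G→A) and, of those,
how many read the target base. Conventions:

* Window 25 bp per end is the common damage-profiler default; it is a
  tunable (`window`, CLI `--damage-window`), not an assumption.
* Reads whose aligned length $L < 2w$ are split at the midpoint: the 5′
  end sees positions $1..\lceil L/2 \rceil$, the 3′ end
  $1..\lfloor L/2 \rfloor$. No base is counted toward both ends, which
  would otherwise double-count the centres of very short fragments.
* N bases (read or reference) are excluded from both counts.
* Only mapped, primary, non-duplicate records enter; the MAPQ filter
  defaults to 0 (include everything) since the mirrored workflow states
  none.
* `substitution = "any"` counts all mismatches over all non-N reference
  bases, for libraries where a deamination-specific count is too narrow.

### Summary statistics

With $r_i$ the defined rates over the window:

* `window_mean` $= \bar r$ — the mean is taken over the *window*, not
  the whole read, because rates are only estimated within the window.
* $N_{db}$ — the length of the run of positions with $r_i > \bar r$
  **starting at position 1** and using **strictly greater**: a literal
  reading of "consecutive significantly damaged bases from the end". A
  perfectly flat profile therefore has $N_{db} = 0$, and an undefined
  position terminates the run.
* $R_{dm}$ — the maximum defined rate (at the 3′ end by default,
  matching how the statistic is conventionally reported).
* `dispersion()` computes the between-sample CV as sample SD (n−1
  denominator) over mean, flagged undefined at mean 0.

## Group comparisons

`compare_groups()` implements the normality-gated procedure: Shapiro–Wilk
on each group (or on the paired differences) at `alpha = 0.05`; if
nothing rejects, a t-test (Welch by default — the pooled-variance test is
available but the source procedure does not say which it used),
otherwise a Wilcoxon test. Unpaired non-normal data use the **rank-sum**
test: the gate's source names only the signed-rank variant, but applies
"Wilcoxon test" to unpaired groups, which is only coherent as rank-sum;
both are implemented and the gate's choice is recorded in `test_used`.
Details:

* Shapiro–Wilk is implemented in the package (Royston's approximation,
  $3 \le n \le 5000$) and verified against `stats::shapiro.test` in the
  test suite, keeping the implementation and its oracle separate.
* Signed-rank zeros are dropped (classic treatment); exact null
  distributions are used for small tie-free samples, the normal
  approximation with continuity correction otherwise.
* t statistics are reported as $|t|$; all p-values are two-sided; no
  multiple-testing correction is applied (matching the mirrored
  procedure).
* Degenerate inputs: all paired differences zero → flagged, $p = 1$;
  a zero-variance group (normality undefined) routes to the
  nonparametric branch.

## The synthetic generator

`simulate_reads()` emulates a trimmed, aligned hair-shaft library — the
aligner's *verdict*, not the aligner: endogenous reads are emitted as
mapped records with uniform start positions, fragment-law lengths,
terminal deamination ($P_i = d_0\,\delta^{\,i-1}$ from each end, applied
to the molecule *before* uniform sequencing error, matching the physical
order), correct all-M CIGAR and MD tags, and a configurable multi-mapped
fraction (MAPQ 0 + `XT:A:R`); exogenous reads are i.i.d. sequence
emitted unmapped. Every read gets a truth row (origin, length,
deamination events per end, multi flag), so each pipeline stage is
testable by parameter recovery.

Defaults state a moderately preserved hair sample and are not tuned:
mean fragment length 50 bp (lognormal, CV 0.25, truncated to 25–150 bp),
endogenous fraction 0.5 (observed range ~0.10–0.93), $d_0 = 0.03$ per
end (observed terminal rates ~0.01–0.05), decay $\delta = 0.75$ (gives
$N_{db} \approx 7$ at the 25 bp window, the magnitude seen in long-stored
keratinised samples), sequencing error $10^{-3}$, multi-mapped fraction
0.3 (observed ~0.14–0.74). The geometric positional decay form is the
standard parametric shape for post-mortem deamination.

`make_study_fixture()` instantiates three study designs with group
parameters taken from the observed regimes: a two-hair-type contrast
(endogenous means 0.83 vs 0.44, SDs 0.073/0.224), a three-level tanning
gradient (means 0.570/0.499/0.099 with the observed SDs — note the first
two levels genuinely overlap, so only the wide contrasts are forced at
n = 5), and matched hair/skin pairs differing in damage-rate dispersion
(d₀ mean ≈ 0.036–0.040, CV 0.29 vs 0.49; the printed skin mean of
"0.004" is internally inconsistent with its printed SD and CV and is
read as 0.040).

**What a green test does not establish.** The generator draws uniform
fragment starts over an i.i.d. reference; real genomes have repeat
structure, coverage bias and fragmentation-site composition effects, and
real multi-mapping is a property of the genome, not a coin flip. Indel
damage, PCR duplicates and quality-score structure are not modelled.
Recovery tests therefore validate the *computation*, not the biology.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; SAM's 1-based POS is
  converted at the boundary. All rates are fractions internally; percent
  rendering happens only in report text (2 decimals).
* $R_{m0}$ with zero mapped reads, CV with mean 0, and damage rates at
  positions with no source base are reported as NA and flagged, never
  silently zeroed.
* `fit_size_trend()` on a constant response returns slope 0, $R^2 = 0$,
  $p = 1$ rather than trusting `summary.lm` at zero total sum of
  squares.
* Comparisons with fewer than 3 samples per group are skipped with a
  warning; every other filtering decision (excluded bins, skipped
  trends) is also surfaced as a warning rather than a silent drop.
* `run_study()` is deterministic: rerunning a config on the same inputs
  is byte-identical, and the manifest records MD5 checksums of every
  written table.

## Known limitations

* SAM text parsing is in-package (so fixtures need no compression
  tooling); BAM support delegates to Rsamtools and treats records
  individually — no mate pairing, CRAM, or random access.
* The size-trend regression inherits the midpoint-grouping caveat above.
* $N_{db}$ compares against the window mean; if a library's damage
  extends beyond the window, the statistic saturates at the window size.
* The Shapiro–Wilk approximation is accurate to ~3 decimals against the
  reference implementation; at $n$ near 5000 both are conservative.
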