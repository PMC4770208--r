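---
title: "Poisson binomial filtering: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poisson binomial filtering: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbfilter)
```

## The problem

Marker-gene surveys (16S rRNA amplicons and relatives) cluster reads into
OTUs at a fixed similarity threshold, typically 97%. Sequencing errors
push otherwise identical reads apart, inflating the number of OTUs and
degrading the accuracy of the representative sequences. Quality filtering
must therefore discard reads likely to carry too many errors — but not so
aggressively that it discards real biology, and not in a way that is
correlated with taxonomy.

`pbfilter` filters each read on the exact probability distribution of its
error *count*, derived solely from its Phred quality scores.

## The error model

A Phred score $q_i$ encodes the probability that base $i$ was miscalled,

$$p_i = 10^{-q_i/10}.$$

Treating base calls as independent, the number of wrong bases in a read of
length $N$ is a sum of independent, non-identically distributed Bernoulli
variables,

$$S_N = \sum_{i=1}^{N} X_i, \qquad P(X_i = 1) = p_i,$$

which follows a Poisson binomial distribution. Its pmf has a closed form
(a sum over all subsets of bases), but that form is useless beyond tiny
$j$; `pbfilter` instead computes it by iterated convolution. Because each
$X_i$ takes only the values 0 and 1, folding base $i$ into the running
distribution $U$ costs one sweep:

$$P(U + X_i = j) = P(U = j)\,(1 - p_i) + P(U = j - 1)\,p_i.$$

`error_distribution()` implements this in compiled code; the enumeration
oracle `brute_force_distribution()` (restricted to $N \le 15$) exists so
the tests can verify the convolution against an independent route, and
uniform-$p$ inputs are additionally checked against the binomial closed
form.

### The confidence quantile $j_\xi$

The filter does not use the whole distribution. `predicted_max_errors()`
grows the pmf terms lazily, $j = 0, 1, 2, \dots$, and stops at the first
$j_{\max}$ with $\sum_{r=0}^{j_{\max}} P(S_N = r) \ge \xi$ (the inequality
is inclusive: a cumulative sum exactly equal to $\xi$ stops there). Terms
beyond $j_{\max}$ are never computed, so the cost is $O(N \cdot j_{\max})$
— small for good reads, which is most reads. Linear interpolation between
the last two cumulative values gives the read's *predicted maximum number
of errors*:

$$j_\xi = j_{\max} - 1 +
  \frac{\xi - \sum_{r=0}^{j_{\max}-1} P(S_N = r)}{P(S_N = j_{\max})}.$$

The read is kept iff $j_\xi \le j_{\mathrm{tol}}$, with
$j_{\mathrm{tol}} = \texttt{uncert} \times L$ for trimmed length $L$
(`compute_jtol()`; the discard rule is strict, so a read sitting exactly
on the tolerance is kept). Defaults: $\alpha = 1 - \xi = 0.005$ and
`uncert` $= 0.01$, i.e. one tolerated error per 100 nt at 99.5%
confidence — $j_{\mathrm{tol}} = 2.5$ at $L = 250$ and $2$ at $L = 200$.

### Numerical choices

* All arithmetic is in double precision, linear space. Term magnitudes
  are bounded below by $\prod_i (1 - p_i)$, which does not underflow for
  realistic read lengths; the full-support normalization test
  ($\sum_j P(S_N = j) = 1$ within $10^{-9}$ at $N$ up to 500) guards this.
* When $P(S_N = 0) \ge \xi$ the interpolation is negative; $j_\xi$ is
  clamped to 0, since a negative predicted error count is meaningless.
* If $P(S_N = j_{\max})$ is exactly zero in floating point (possible only
  through precision loss), $j_\xi$ falls back to $j_{\max}$, which is the
  conservative integer choice; $j_\xi$ is also clamped above at $N$.
* `poisson_predicted_max_errors()` applies the identical
  stopping-and-interpolation rule to Poisson pmf terms with
  $\lambda = \sum_i p_i$, generated by the recurrence
  $P(j) = P(j-1)\,\lambda/j$ (log-space evaluation if $e^{-\lambda}$
  underflows). The approximation requires every $p_i \ll 1$: a single
  low-quality base breaks it, and the regression tests pin the direction
  of the failure (one $p = 0.9$ base among 200 clean ones makes the
  Poisson $j_\xi$ substantially larger than the exact one, i.e. it
  discards reads the exact model would keep).

### What $\alpha$ does and does not guarantee

The intended reading of $\alpha = 1 - \xi$ is "the probability that the
read carries more than $j_\xi$ errors". At the integer level this holds
by construction for the *stopping point*: since the cumulative reaches
$\xi$ at $j_{\max} = \lceil j_\xi \rceil$,

$$P(\text{true errors} > \lceil j_\xi \rceil) \le \alpha,$$

and the simulation suite confirms it with wide margin. The *interpolated*
$j_\xi$, however, lies below $j_{\max}$, and error counts are integers:
the event $\{\text{true} > j_\xi\}$ equals $\{\text{true} \ge j_{\max}\}$,
whose probability is

$$1 - \textstyle\sum_{r < j_{\max}} P(S_N = r) \;=\; \alpha +
  \mathrm{frac}\cdot P(S_N = j_{\max}) \;\ge\; \alpha,$$

where $\mathrm{frac} \in (0, 1]$ is the interpolation fraction. The
excess is about half a pmf term at the quantile, which for good reads
(small $\lambda$, coarse pmf) is much larger than $\alpha$ itself: a
constant-Q40, 250-nt read has $j_\xi \approx 0.81$ but a
$1 - e^{-0.025} \approx 2.5\%$ chance of at least one error. The
calibration suite measures this honestly: the strict exceedance over the
interpolated $j_\xi$ on 50,000 calibrated reads is a few percent, not
$\alpha$, while the exceedance over $\lceil j_\xi \rceil$ stays below
$\alpha$. None of this affects the *filtering decision* in the usual
regime, where $j_{\mathrm{tol}}$ sits well above $j_\xi$ for good reads
and well below it for bad ones; it only means that the fractional part of
$j_\xi$ should not be read as a sharp per-read guarantee level.

## The pipeline

`run_pipeline()` executes, in fixed order:

1. **Contig assembly** (paired mode). Mates are matched by file order;
   the reverse mate is reverse-complemented and aligned to the forward
   read by Needleman–Wunsch dynamic programming with *free terminal gaps*
   (overlap mode), so non-overlapping tails cost nothing. Consensus: a
   column where one read is gapped keeps the other read's base and
   quality; agreeing bases keep the base; conflicting bases take the
   higher-quality base when the quality difference exceeds `deltaq`
   (default 6) and `N` otherwise. In every double-coverage column the
   consensus quality is the column *maximum* of the member qualities —
   deliberately optimistic, since the two observations agree or the
   better one wins. Scoring defaults are the conventional
   match $+1$ / mismatch $-1$ / gap $-2$; correctness is established
   against an exhaustive alignment oracle, not tied to these constants.
   Traceback tie-breaking (diagonal, then gap-in-second, then
   gap-in-first; end cell scanned in a fixed order) is pinned so reruns
   are byte-identical.
2. **Truncation.** Reads (or contigs) of length $\ge L$ are cut to their
   first $L$ bases; shorter ones are discarded with reason `short`.
   Truncating to a common length keeps $j_{\mathrm{tol}}$ comparable
   across reads and removes the low-quality 3' tails.
3. **Error prediction.** $j_\xi$ at confidence $1 - \alpha$, per read, on
   the truncated sequence (it must precede collapsing, because the
   representative is chosen by least predicted errors).
4. **Collapsing and filtering.** Identical sequences are grouped
   (`collapse_reads()`); each group is judged by the member with the
   smallest $j_\xi$ (`filter_reads()`). Rationale: two biologically
   unrelated reads essentially never become identical through sequencing
   error, so one high-quality copy vouches for all its duplicates. This
   also counters a systematic bias: read quality is partly
   taxon-correlated (sequence composition affects base calling), so
   naive per-read filtering depletes some taxa disproportionately.
   Collapsing first lets the well-read copies of a noisy taxon rescue
   the rest. Group ordering (multiplicity descending, then sequence) and
   representative ties (first in input order) are fixed for determinism.

Outputs are a kept FASTQ, a discarded FASTQ (reason tagged in the
header), a mothur-dialect names file when collapsing, and a per-read
TSV report. `exec/pbfilter` wraps the same function for shell use.

Degenerate inputs: an empty FASTQ is an empty result, not an error; a run
in which nothing survives warns rather than fails; ambiguity codes other
than `N` are rejected at parse time as signs of upstream corruption.
Bases called `N` carry their emitted quality (typically 2) through
`phred_to_prob()` like any other base — the model consumes only quality
scores.

## The simulator

`simulate_reads()` exists so that calibration claims are testable without
any reference dataset: it draws a quality string from a profile, then
flips each base (to a uniformly chosen different base) with *exactly* the
probability the emitted score encodes. Emitted qualities are therefore
perfectly calibrated descriptions of the true error process, and any
miscalibration measured downstream is attributable to the error model
alone. Profiles: `qprofile_constant(q)` and `qprofile_decay(q5, q3)`
(linear 5'→3' decline, the classic 454/IonTorrent shape), optionally with
per-base jitter and a per-read quality offset (`shift_sd`) reflecting the
read-to-read quality variation real machines show.
`simulate_two_taxon()` couples two templates to different profiles to
reproduce taxon-correlated quality, the situation the collapse remedy
addresses; the pipeline test verifies that collapsing strictly increases
the retention of the noisy taxon.

What the simulator does *not* emulate: indels and homopolymer
miscalls (the model is positionwise and indel-agnostic; platform
simulators own that realism), chimeras, PCR substitution errors
(errors present before sequencing carry good quality scores and are
invisible to any quality-based filter), quality-score miscalibration, and
correlated errors. Passing calibration tests on simulated data therefore
shows the mathematics is right, not that any platform's quality strings
are truthful — on real data the filter inherits whatever miscalibration
the base caller has.

Problem sizes used by the test and acceptance suites — 50,000 reads of
250 nt for calibration, 1,000 random probability vectors up to $N = 500$
for normalization, 200 enumeration cross-checks at $N \le 12$, all
alignment pairs at lengths $\le 8$ against the exhaustive oracle — were
chosen so each property is measured with comfortable statistical margin
while the whole suite runs in about a minute.

## Known limitations

* Error independence and quality truthfulness are assumptions inherited
  from the model; 454-style homopolymer qualities violate them by
  design.
* The assembler matches mates by file order and does not re-pair by id.
* Collapsing is exact string identity; near-duplicates (one error apart)
  are separate groups by design — merging them is the job of downstream
  denoisers/clusterers, not of the filter.
* The interpolated $j_\xi$ is anti-conservative as a per-read guarantee
  at the fractional level (see above); use $\lceil j_\xi \rceil$ when an
  integer error budget with a strict $\alpha$ guarantee is needed.
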