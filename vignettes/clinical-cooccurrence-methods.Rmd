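---
title: "Counting clinical co-occurrences: model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting clinical co-occurrences: model, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClinCooccur)
```

# The model

`ClinCooccur` estimates the pairwise relatedness of clinical entities from
longitudinal note text by counting how often two dictionary terms (or the
concepts they map to) appear within the same temporal window of the same
patient's record. The pipeline has four stages — annotate, bin, count,
derive — and each stage's contract is deliberately simple enough to be
checked against an independent oracle.

## Temporal binning

Clinical events are only loosely aligned with the notes that document them,
so concurrency is defined over *bins* rather than single notes. For a
patient whose first note falls at time $t_0$, a bin width $w$ (days), a
per-patient random offset $r \in [0, w]$, and a note at $t$ days after
$t_0$, the bin index is

$$\mathrm{BIN}_p(w, r, t) = \left\lfloor \frac{t + r}{w} \right\rfloor.$$

The floor gives half-open bins: bin $k$ covers $t + r \in [kw, (k+1)w)$.
Two consequences are worth stating. First, notes more than $w$ days apart
can never share a bin, for any offset — a property the test suite checks
over randomized $(r, t)$ grids. Second, notes *less* than $w$ days apart
may still straddle a boundary; the random offset makes that straddling
unbiased with respect to calendar structure (weekday effects, batch
timestamping), which is its purpose. All notes hashed to one bin have
their annotation sets unioned; within-bin multiplicity is discarded (a
binary occurrence model — a term mentioned five times in a bin counts
once).

The supported widths are 1, 7, 30, 90, 180, 365 and $\infty$ days; at
$w = \infty$ each patient's record is one bin, so bin-level and
patient-level aggregation coincide there by construction.

## Aggregation modes and the universe size

Counts are aggregated two ways. *Per bin*: every qualifying bin contributes
one count, so a patient with a chronic condition contributes many. *Per
patient*: a patient contributes at most one count per entity or pair,
however many bins qualify; per-patient singleton counts are therefore
independent of the width. Every count container carries its universe size
$N$ — the number of non-empty bins at that width, or the number of eligible
patients — because all downstream statistics divide by it. Contingency
tables over per-patient counts must use the patient count as $N$, which is
exactly the $\infty$-day bin count.

## Association statistics

With $f(X)$, $f(Y)$, $f(X,Y)$ and $N$, the 2×2 table is filled as
$A = f(X,Y)$, $B = f(X) - f(X,Y)$, $C = f(Y) - f(X,Y)$,
$D = N - [f(X) + f(Y)] + f(X,Y)$, and the package computes the odds ratio
$AD/BC$, relative risk, the $\chi^2$ statistic with margin-derived expected
cells, the $G$ statistic $2\sum O \ln(O/E)$ (with $0 \ln 0 = 0$), the
conditional $P(Y\,|\,X) = P(X,Y)/P(X)$ and the lift
$P(Y\,|\,X)/P(Y) = N f(X,Y) / (f(X) f(Y))$, which equals 1 under
independence and is symmetric in its arguments.

Zero denominators are reported as `NA` with a reason code rather than as
infinities, because silently adding pseudo-counts would distort counts
reproduced from published files; the Haldane $+0.5$ correction is available
behind an explicit flag and is applied to all four cells of the test
statistics only — probabilities and lift always use raw cells.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `minNotes` | 10 | notes | eligibility floor for a usable longitudinal record |
| `minSpanDays` | 365 | days | "at least one year", inclusive at the boundary; 365 matches the day-based width convention (365.25 would shift almost no patients) |
| `widths` | 1, 7, 30, 90, 180, 365, ∞ | days | the canonical ladder from intra-day to whole-record concurrency |
| `minLength` | 4 | characters | shorter strings are overwhelmingly ambiguous abbreviations |
| negation `window` | 6 | tokens | typical NegEx-style scope; configurable per call |
| `threshold` | 100 | count | serialization filter: rows with counts ≤ 100 are withheld from files (small counts are noisy and dominate file size); in-memory counts remain exact |
| `liftThreshold`, `minCount` | 2, 1 | — | edge criteria for correlated-feature groups |
| `seed` | — | — | keys all randomness; identical seed ⇒ byte-identical export |

The per-patient offsets are drawn from an RNG stream keyed on
`(seed, patient, width)`, not from a global stream: patients are mutually
independent, insertion order is irrelevant, and each width gets a fresh
draw. Whether the original design shared one offset across widths is not
determinable; redrawing per width is the cleaner independence assumption
and is what the width-monotonicity tests assume (they compare *trends*, not
matched bins).

# Annotation policy

Dictionary matching is case-insensitive, longest-match-wins,
leftmost-first and non-overlapping over punctuation-stripped tokens
(maximal munch — the standard concept-recognizer convention, and the only
deterministic choice that needs no corpus statistics). Normalization is
minimal on purpose: lowercase, strip punctuation at token boundaries,
collapse whitespace. Anything heavier (stemming, spelling correction)
would make the matching unauditable against the lexicon files.

Negation is a trigger-window approximation of NegEx: a mention is negated
if a pre-trigger phrase ends within six tokens before it or a post-trigger
phrase begins within six tokens after it. History and family-history are
section-based: a mention is flagged when the nearest preceding section
marker belongs to the corresponding marker list. The trigger and marker
lists ship as editable plain-text files (`inst/extdata/`).

Whether negated or history mentions were included in any given published
count set is generally not recoverable from the counts themselves, so the
inclusion policy is exposed as three booleans. The default — exclude
negated and family-history mentions, include history mentions — reflects
the most common reading (a negated mention is evidence of absence; a
family-history mention is about a relative; the patient's own history is
still the patient), but it is a declared choice, not a verified fact.

Ambiguity suppression (e.g. preferring the device reading of "clip" over
the peptide drug) is driven by an explicit suppressed-pairs file rather
than a built-in likelihood model: the original interpretation ranking was
corpus-derived and is not reconstructible, so the package takes the ranking
as data. Concept-level counting restricts, by default, to terms that map
unambiguously onto drug or disease concepts, then normalizes drugs to
ingredients via the supplied mapping.

# The synthetic corpus: what it does and does not emulate

The simulator exists to make every downstream stage testable with a known
answer. It emulates: per-patient note streams (default 100 patients with
10–12 notes each, i.e. over a thousand notes — the scale used for
validating the counting path), uniform timestamps over a 730-day span
(long enough that essentially all patients pass the one-year eligibility
filter), notes composed of dictionary term tokens plus out-of-dictionary
filler, and planted pairwise associations implemented by co-injecting both
terms into the same note with a configured probability $p$ — the simplest
mechanism that guarantees same-bin co-occurrence at every width and whose
analytic footprint is computable: with $k$ background draws from a
vocabulary of $V$, the per-note joint probability is
$p + (1-p)\,k(k-1)/(V(V-1))$ and each marginal is $p + (1-p)\,k/V$, giving
a closed-form lift that the estimated lift must recover within Monte-Carlo
error.

It deliberately does **not** emulate: clinical language (the negation and
section logic is exercised on small hand-written prose fixtures instead),
visit-process structure (no bursts, no episodes — timestamps are uniform
because no visit model is specified and uniformity exercises every width),
realistic vocabulary frequency skew, or inter-patient heterogeneity.
Passing the validation therefore certifies the *transformation* — text →
bins → counts → statistics — not the annotator's behaviour on real
clinical prose, which depends on the user's lexicon quality.

Because generated term tokens are unique to their term and fillers are
guaranteed out-of-dictionary, annotation of synthetic text is exactly
invertible; the suite asserts that annotation recovers the generator's
ground truth verbatim, which pins any count discrepancy onto the counting
stages.

# Validation design and numerical choices

Three independent implementations must agree exactly on every singleton and
pair count, for all seven widths and both modes, on a seeded 100-patient
corpus:

1. the production counter (sharded `data.table` joins; shards reduce by
   summation per-bin and by patient-union per-patient, so the result is
   invariant to worker count and processing order — asserted for 1, 2 and
   8 shards);
2. a single-threaded reference counter (a naive double loop with a
   hash-map accumulator, no vectorization);
3. the generator's ground truth (binary occurrence matrices and
   cross-products per patient, re-deriving bin indices inline from the
   floor formula).

Exact integer agreement — not tolerance-based — is the acceptance surface,
alongside property suites over 200 randomized fixtures (count inequalities
$f(X,Y) \le \min(f(X), f(Y))$, per-patient ≤ per-bin, per-patient at any
finite width ≤ per-patient at $\infty$; table identities $A+B+C+D = N$,
$P(Y|X)P(X) = P(X,Y)$, lift symmetry). Stochastic checks (planted joint
frequency, lift recovery at 10,000 bins, null enrichment calibration at
1,000 cohorts) use 3-standard-error bands derived from their own sampling
models; the lift band uses the delta-method standard error of the
log-lift, $\sqrt{1/f(X,Y) + 1/f(X) + 1/f(Y)}$, which ignores the
(variance-reducing) positive covariances and is therefore conservative.

Degenerate inputs are defined, not avoided: empty note text annotates to an
empty mention list; an empty bin list counts to empty tables with $N = 0$;
a bin with fewer than two IDs contributes no pairs; an ID-free bin still
counts toward $N$. Serialized count files are canonical — sorted, header-
less, LF-terminated, integers only — so a fixed seed reproduces a
byte-identical export, and round-trip identity is asserted at the byte
level. The published row ordering and header convention are not
documented anywhere; sorted header-less output was fixed here for
determinism and diffability. Writes go to a temporary file followed by an
atomic rename, so an interrupted export never leaves a truncated file.

# Design choices where the design was open

* **Enrichment adjustment.** The dependency adjustment raises a term's
  expectedness using its co-occurrence with the cohort-defining term: the
  expected count switches from $n\,f(y)/N$ (hypergeometric null) to the
  conditional rate $n\,f(x,y)/f(x)$, with an upper binomial tail at that
  rate. This conditional-rate rule is one admissible concretization of
  co-occurrence-adjusted enrichment; it is labelled as such and the
  unadjusted columns are always reported alongside.
* **Multiple testing.** Benjamini–Hochberg across tested IDs — the default
  a practitioner would reach for when a procedure is required but none is
  mandated.
* **Feature groups.** Connected components of the lift-thresholded
  co-occurrence graph, not cliques: parameter-free, deterministic and
  sufficient as input to a group penalty. Components over-merge through
  chains by construction; that is visible in, and controllable by, the two
  edge thresholds.
* **Tail convention.** Enrichment p-values are upper-tail
  (over-representation); $\chi^2$ and $G$ are the usual two-sided
  statistics.

# Known limitations

* The annotator is a dictionary matcher with a window-based NegEx
  approximation, not a full NegEx regular-expression engine; trigger scope
  subtleties (conjunction breaking, pseudo-negation) are only as good as
  the supplied trigger lists.
* Counting is in-memory and single-machine; the shard/reduce contract
  mirrors a distributed design, but corpora beyond desk scale need an
  external backend honouring the same merge algebra.
* Calendar-aware bins (months, years as calendar units) and time zones are
  out of scope; timestamps are plain fractional days.
* Statistics are screening statistics over co-mention counts: they
  quantify documentation co-occurrence, not causal or even clinical
  co-occurrence, and inherit every bias of who gets notes written about
  what.
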