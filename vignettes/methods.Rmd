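---
title: "Models and methods behind drbank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind drbank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drbank)
```

This vignette documents the statistical and representational choices the
package makes: the annotation data model, the agreement statistics, the
classification baseline, the synthetic-data generator, and the places
where the design was genuinely open and a decision had to be made.

## The data model

A relation bank annotates plain source documents with binary discourse
relations. Four relation types are distinguished. *Explicit* relations
are anchored by a closed-class connective with a recorded span; *AltLex*
relations by an open-class alternative lexicalization whose span is by
definition part of Arg2; *Implicit* relations have no textual anchor —
the annotator inserts the connective string that best expresses the
inferred relation, or the marker `NONE` when the inferred sense is
Continuation, Background or Circumstance, for which no connective can be
inserted; *NoRel* marks a sentence with no coherent link to prior text.
These constraints are exactly what `validate_record()` enforces, and the
readers report violations rather than silently repairing them, because a
corpus audit is a primary use case.

**Offset convention.** Spans are 0-based and half-open, `[start, end)`.
The stand-off format itself does not disclose end-inclusivity, so this
was an open decision: half-open makes span length equal `end − start`,
makes abutting spans concatenate losslessly, and matches how most
programming languages slice strings. A `standoff_dialect(end_inclusive =
TRUE)` flag converts inclusive-end input on the fly, so either dialect of
distributed data can be read. For the same reason the total column count
of the pipe-delimited line (27 here, inferred from the documented example
rows) is a dialect parameter rather than a constant.

**Sense taxonomy.** Two tiers: 16 types, 9 of which carry 2–4 subtypes,
for 31 leaf categories. Annotation records must carry leaf labels (the
bare type cannot be chosen when subtypes exist); aggregate tables report
at type level. Both granularities therefore exist in the wild, and
validation has a `strict` switch: strict for records, lenient for
table-derived fixtures. The four-class generalization (Comparison,
Contingency, Temporal, Expansion) is a fixed total surjection from the 16
types and ignores subtypes.

## Agreement statistics

**Token identification.** Two annotators need not mark the same tokens,
so identification agreement is the ratio of matched tokens over matched
plus unmatched: `n_common / (n_a + n_b − n_common)`. Tokens match when
their span sets share at least one character — the weakest defensible
reading of "overlapping", chosen so that subordinator/adverbial boundary
disputes do not destroy identification credit; the exact/partial
argument criteria handle boundary quality separately.

**Matching procedure.** Pairing must be one-to-one. The package pairs
greedily left-to-right over annotator A's tokens, choosing among the
unmatched overlapping candidates the one with the *earliest end* (larger
overlap, then position, break ties). For families of disjoint token
spans — the realistic case — this greedy provably attains the maximum
matching; a largest-overlap-first rule does not (a long A-token can steal
the only partner of its right neighbour), which is why earliest-end is
primary. An exhaustive maximum-bipartite-matching mode (Kuhn's
augmenting paths) is kept as an independent oracle and the test suite
checks the two agree on randomized inputs.

**Argument agreement** is computed only on matched pairs. *Exact* means
the two span sets cover the identical set of characters (this subsumes
"identical or fully overlapping": discontinuity that does not change
coverage is immaterial); *partial* means one shared character. Exact is
by construction never above partial, and the suite asserts this
monotonicity across noise levels. An empty pair list is an error, not a
ratio of 0/0.

**Sense agreement.** Because a token may carry up to two senses,
annotators agree on a token if at least one sense coincides, at the
31-leaf granularity. Chance-corrected agreement uses Cohen's kappa with
*per-annotator* marginals — the reported statistic distinguishes observed
from expected agreement, which pooled (Scott-style) marginals would not
reproduce. Kappa over first-sense labels is what the package reports;
how multi-sense tokens should enter the chance model is genuinely
underdetermined, and using first senses only is the conservative,
documented choice. Kappa is undefined when expected agreement is 1 (two
constant, identical annotators); this raises an error rather than
returning NaN.

## The classification baseline

The experiment asks how far the connective surface string alone goes as
a sense predictor. With a single categorical feature, any
confidence-rated rule learner's decision surface collapses to one
constant label per connective, so the package trains exactly that: the
training-majority label per connective (confidence = its relative
frequency), with the global majority as fallback for unseen connectives.
Ties break by higher global prior, then lexicographically, making
training deterministic. This surrogate is Bayes-optimal within the
hypothesis class the feature affords, which is what licenses the
closed-form oracle below.

Three sense-slot scenarios build the instance set: first sense only;
second sense (falling back on the first when absent); both senses (one
extra instance per doubly-sensed token). Cross-validation uses seeded,
non-stratified uniform fold assignment — stratification was not stated
for the original experiments, and with ~10 well-populated classes at the
corpus sizes involved it changes nothing beyond noise. The learning
curve fixes one seeded held-out test set and grows nested training
subsets by a constant increment, so curve points differ only in training
data. Accuracy equals micro-averaged recall; macro-F1 averages class F1
without weighting; a class never predicted gets precision 0 and is
flagged rather than dropped.

The reference corpus' published accuracies (90.9% class-level first
sense, 69.2% type-level, 54.5% cross-domain) require the real annotated
corpora, which cannot be redistributed; they are documented as reference
points, not test targets. The binding checks are the synthetic ones
below.

## The synthetic-data generator

`synth_config()` states a world; its defaults are the published corpus
conditions wherever those are stated:

* relation-type mix 2636 / 3001 / 193 / 29 over 24 documents;
* explicit connective inventory: the 27 published ambiguous connective
  types with their token counts as sampling weights and their type-level
  sense inventories as conditional support, plus five unambiguous
  connectives carrying the remaining 1308 tokens so the ambiguous share
  is 1328/2636;
* a 7.4% multiple-sense rate, with ordered (sense1, sense2) pairs drawn
  from the 16 published pair rows;
* implicit sense weights equal to the published implicit sense column;
  `NONE` is emitted exactly for the three marker-compatible senses;
* IMRAD section quotas proportional to the published segment totals.

Where the source states no value a single realistic choice was made and
is not revisited: the first-listed sense of an ambiguous connective
receives conditional probability 0.7 (clear majority, non-degenerate
ambiguity), the remainder is spread uniformly; subtypes are drawn
uniformly within a type; argument spans are 4–8 filler words. Filler
text is drawn from a fixed nonsense lexicon that by construction shares
no string with any connective, so planted offsets are unambiguous ground
truth. With these defaults the class-level closed-form optimum of the
connective feature comes out at 90.4% — emergent from the stated world,
not calibrated.

The second-annotator model (`perturb_config()`) applies independent
per-record noise: missed explicit tokens (deletion), spurious tokens
(planted inside Arg1, so they never collide with true connectives),
boundary jitter on the outer argument endpoints (redrawn when it would
produce an empty or out-of-bounds span, and constrained to preserve
AltLex containment), and sense substitution uniform over the
alternatives at the label's own granularity. Each process has a clean
closed-form signature — deletion rate `d` leaves an overlap ratio of
`1 − d`, jitter rate `p` an exact-match ratio of `1 − p`, confusion rate
`c` a sense agreement of `1 − c` on single-sense records — and the
acceptance suite recovers all three within three binomial standard
errors at 2000 relations.

**What a green test does and does not establish.** The generator
emulates the *bookkeeping* of a relation bank: offsets, field layout,
distributions, noise. Its text is not language; arguments are filler,
connectives never interact with context, and sense draws are i.i.d.
given the connective. Green synthetic tests therefore certify the
machinery — parsing, matching, counting, cross-validation — and the
convergence of estimators to their closed forms; they say nothing about
linguistic difficulty, and in particular the synthetic CV accuracy is
*not* a reproduction of the published 90.9%.

## Reconstructed-table fixtures

`fixture_from_tables()` rebuilds deterministic corpora whose statistics
reproduce the published summary tables cell for cell, at the granularity
the tables use (type-level senses, hence lenient validation). Two
printed rows of the segment-distribution table are internally
inconsistent (Conjunction cells sum to 749 against a printed total of
754; Temporal to 374 against 515, apparently a missing Results cell).
The fixtures carry the printed cells and attach the printed row totals
as a denominator override; `imrad_distribution()` uses the override for
percentages and flags the inconsistent rows. Nothing is repaired,
because the package's job on reference data is to reproduce and expose,
not to improve. Two typographic artifacts in the ambiguity inventory
("nally", "Cirsumstance") are restored to their canonical spellings
("finally", "Circumstance") with counts untouched.

## Degenerate inputs and numerical conventions

* Empty span-set fields parse to the empty span set; empty *spans*
  (`start ≥ end`) are always errors.
* Probability rows must sum to 1 within 1e-9; fold counts must not
  exceed instance counts; learning-curve increments must divide the pool.
* All randomness flows through explicit integer seeds, and the seeded
  helpers restore the caller's RNG state, so library calls never
  perturb a user's simulation stream.
* F1 is 0 when precision and recall are both 0; overlap ratio is 1 when
  both annotators marked nothing (vacuous agreement).

## Limitations

Attribution annotation, argument syntactic categories, connective
identification in raw text, and implicit-sense prediction are out of
scope. The classifier deliberately uses no features beyond the
connective string. Section labels are inputs (sidecar files), not
inferred; automatic rhetorical zoning is not attempted. The generator's
sections are contiguous blocks, which suffices for distribution tests
but does not model real interleaved document structure.
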