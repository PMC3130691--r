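# drbank

Tools for building, validating and analyzing **discourse relation banks**
in the PDTB stand-off style, aimed at corpus developers and text-mining
researchers working with full-text scientific (especially biomedical)
articles.

A discourse relation is an informational link — causal, temporal,
contrastive, expansive — between two abstract objects (events, states,
propositions) mentioned in text. A relation bank annotates, over plain
source documents, four kinds of relation tokens (Explicit, Implicit,
AltLex, NoRel), each with two argument spans (Arg1, Arg2), an anchoring
connective where one exists, and up to two senses drawn from a two-tier
taxonomy of 16 types and 31 leaf categories, generalizable to the four
classes Comparison / Contingency / Temporal / Expansion. Annotations are
stored stand-off: pipe-delimited flat files whose fields carry character
offsets into the untouched source text.

The package implements:

* **Data model and taxonomy** — span sets (0-based, half-open,
  discontinuity-aware), sense labels validated against the 31-leaf
  hierarchy, per-relation-type well-formedness checks
  (`build_taxonomy()`, `validate_record()`, `to_pdtb_class()`).
* **Stand-off I/O** — reading/writing the pipe-delimited representation
  with exact round-tripping, span grammars `start..end(;start..end)*`,
  rhetorical-section sidecars (`read_corpus()`, `serialize_relation()`).
* **Inter-annotator agreement** — token identification overlap
  (`n_common / (n_a + n_b − n_common)`), exact/partial argument match,
  sense agreement under the at-least-one-shared rule, and Cohen's kappa
  `κ = (A_o − A_e)/(1 − A_e)` with per-annotator chance marginals
  (`match_connectives()`, `cohens_kappa()`, `agreement_report()`).
* **Corpus statistics** — relation-type, sense, connective-ambiguity and
  IMRAD-segment distribution tables (`relation_type_distribution()`,
  `ambiguity_table()`, `imrad_distribution()`).
* **Sense classification** — the connective-string-only baseline: a
  per-connective majority-rule model (the decision surface a boosted rule
  learner reduces to under a single categorical feature), three
  sense-slot scenarios, seeded k-fold cross-validation, learning curves
  and cross-domain transfer (`build_instances()`, `cross_validate()`).
* **Synthesis** — a seeded generator of corpora with known ground truth, a
  controlled second-annotator noise model (span jitter, missed/spurious
  tokens, sense confusion), deterministic fixtures reconstructing the
  published summary tables, and the closed-form optimum
  `Σ_c p(c)·max_l p(l|c)` of the connective-only classifier
  (`generate_corpus()`, `perturb_annotations()`, `fixture_from_tables()`,
  `closed_form_bayes_rate()`).

## Worked example

Generate a synthetic bank under the package's stated-world defaults
(published relation-type mix, ambiguity inventory, 7.4% multi-sense
rate), derive a noisy second annotator, and measure agreement and
classification:

```r
library(drbank)

cfg <- synth_config(n_relations = c(Explicit = 500, Implicit = 300,
                                    AltLex = 40, NoRel = 5),
                    n_docs = 4, seed = 42)
corp <- generate_corpus(cfg)
#> <annotated_corpus> 4 document(s), 845 relation(s)

noisy <- perturb_annotations(corp, perturb_config(
  span_jitter_p = 0.1, delete_p = 0.05, sense_confusion_p = 0.1, seed = 43))
agreement_report(corp, noisy)
#>      group          statistic      value
#> 1 explicit connective_overlap 0.94444444
#> 2 explicit         Arg1_exact 0.90000000
#> ...
#> 7 explicit        sense_kappa 0.88414979
```

The recovered statistics track the planted noise: a 5% deletion rate
leaves a connective overlap near 0.95, a 10% jitter rate an exact-match
ratio near 0.90, a 10% confusion rate a sense agreement near 0.90 —
the basis of the package's parameter-recovery tests.

```r
inst <- build_instances(corp, slot = "first", granularity = "class")
cross_validate(inst, k = 10, seed = 44)
#> <eval_result> accuracy 0.894, macro-F1 0.685 (n = 500)
closed_form_bayes_rate(cfg, "class")
#> [1] 0.9041313
```

Ten-fold CV accuracy (89.4% at n = 500) converges on the closed-form
optimum of the connective-only feature (90.4%) as the corpus grows. The
zero F1 for Temporal illustrates a real property of the baseline: a class
is lost when no connective has it as majority sense.

Reconstructed reference tables:

```r
head(ambiguity_table(fixture_from_tables(5)), 3)
#>  connective n_senses                                                          senses tokens
#> accordingly        2                                              Cause, Conjunction      2
#>    although        2                                            Concession, Contrast     76
#>         and        6 Cause, Concession, Conjunction, Continuation, Purpose, Temporal    274
#> Total: 1328
```

## Command line

```sh
Rscript inst/cli/drbank.R simulate --out corpus/ --seed 42
Rscript inst/cli/drbank.R validate corpus/
Rscript inst/cli/drbank.R stats corpus/ --table ambiguity
Rscript inst/cli/drbank.R agreement corpus/ annA/ annB/
Rscript inst/cli/drbank.R classify corpus/ --granularity class --folds 10
```
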