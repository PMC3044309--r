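---
title: "Semantic hypothesis testing on tissue-microarray data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic hypothesis testing on tissue-microarray data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmatriad)
library(dplyr)
```

## The problem

A tissue microarray (TMA) assembles hundreds of small tissue cores from
different patient samples on one slide, stains them all for a single marker
(an antibody), and scores each core on an ordinal categorical scale
(typically staining intensity 0--3). Most hypotheses a TMA experiment can
decide have the same triadic shape:

> In a biological condition *A*, an entity *B* is positively or negatively
> correlated with an entity *C*.

For example: *reduced expression of Apaf-1 in colon cancer correlates with
high-grade phenotype*. Here the condition *A* is "colon cancer" (a shared
property of the samples), the classifier *B* is "Apaf-1 staining intensity
= 0" (an attribute plus a hypothesis-describing value set), and the
dependent property *C* is "histologic grade = High-grade".

`tmatriad` turns such a statement into a decision procedure over a TMA
database represented as RDF:

1. the relational tables are mapped row-by-row to RDF triples under a
   declarative mapping rule;
2. the triadic hypothesis is compiled into **four** conjunctive count
   queries, one per cell of a 2×2 contingency table;
3. the four counts feed **Fisher's exact test**, and the hypothesis is
   supported when the two-sided p-value falls below a threshold
   (default `alpha = 0.01`).

## Hypothesis model and complementary value sets

Every categorical attribute carries a context-dependent *permissible value
set* registered up front (e.g. grade in colon cancer is
`Low-grade < Intermediate-grade < High-grade`; Apaf-1 intensity is
`0 < 1 < 2 < 3`). A hypothesis states only the hypothesis-describing values;
the *complementary* value set is inferred as the permissible set minus the
stated values. `{High-grade}` has complement
`{Low-grade, Intermediate-grade}`, `{0}` has complement `{1, 2, 3}`. A value
set equal to the whole permissible set (or empty) leaves nothing to compare
against and is rejected as a degenerate hypothesis.

The classifier splits the cores matching the shared property into **Core
Collection A** (hypothesis values) and **Core Collection B** (complement);
the distributions D1 and D2 of the dependent property within the two
collections are what the test compares. Binarizing a multi-level attribute
(3-level grade → High vs rest) *is* the hypothesis/complement partition —
there is no separate "exclude intermediate" mode, because the complement is
defined over the full permissible set.

```{r model}
model <- hypothesis_model(
  demo_registry(),
  shared_value = "Colon cancer",
  classifier_attribute = "Apaf-1 Intensity", classifier_values = "0",
  dependent_attribute = "HistologicGrade", dependent_values = "High-grade",
  direction = "negative"
)
model
```

## Query generation

Four count queries are generated by a fixed value-set assignment: the
classifier uses its hypothesis set in plans 1 and 3 and its complement in
plans 2 and 4; the dependent property uses its hypothesis set in plans 1 and
2 and its complement in plans 3 and 4; the shared property is a constant in
all four. The assignments therefore cover the 2×2 of
{hypothesis, complement} × {hypothesis, complement}, and every pair of
permissible values is matched by exactly one plan (a property the test suite
checks by brute-force enumeration over the value product).

Each plan counts `count(distinct ?cr)` over a canonical basic graph pattern:
core → slide → experiment linkage, core → sample → shared-property match,
and the classifier and dependent matches (against the staining-result table
for marker intensities, against the sample-attribute table for clinical
attributes). Set membership is a disjunction, realized by evaluating one
conjunctive query per member value and unioning the distinct cores — so no
SPARQL `FILTER` or datatype machinery is ever needed; ordinal threshold
queries ("intensity > 1") are likewise expanded at generation time into the
explicit set of permissible values above the threshold, in registry order.

The count unit is the **core**, not the sample or slide: a sample
contributing several cores contributes each of them. The stated direction of
the correlation is descriptive metadata only; the test is two-sided.

## The triple store and query evaluation

The RDF layer is an in-memory, duplicate-free triple table. Subjects follow
`<base>/<table>/<pk>`, predicates `<base>/vocab#<name>`; foreign-key columns
become object-URI triples linking rows, other columns become plain string
literals, and a missing value simply emits no triple. Predicate names are
taken verbatim from the mapping rule — the conventional TMA vocabulary mixes
styles (`Name` maps to `hasName`, while `ExpType` maps to itself) and the
package does not second-guess that by auto-prefixing.

Conjunctive queries are evaluated by joining per-pattern match tables on
shared variables, most-selective pattern first (with a preference for
patterns connected to already-bound variables, which avoids cross products).
The contract is only that counts are correct; the test suite enforces it by
comparing against a brute-force evaluator that enumerates every variable
assignment over the graph's terms on small random graphs. Because the only
consumer is the count-query generator, the evaluator deliberately supports
nothing beyond basic graph patterns — no `OPTIONAL`, `UNION`, property paths
or entailment.

One representational subtlety: URI bindings are tracked distinctly from
literal bindings (a URI and a literal with the same spelling never join),
which keeps join semantics exact even though literals carry no datatype
tags.

## Fisher's exact test

The four counts are arranged with classifier as columns and dependent as
rows (n11 = both hypothesis, n12 = classifier complement, n21 = dependent
complement, n22 = both complement); plan *i* fills cell *i* in that order.
This orientation matches the published worked example's reading
(26, 4, 6, 19); the two-sided p-value is invariant to it.

Under the null, with all margins fixed, the top-left cell follows the
hypergeometric distribution; the pmf is computed via log-factorials
(`lchoose`) for overflow safety. The two-sided p-value uses the
probability-mass rule: the sum of probabilities of every feasible table no
more probable than the observed one, with a `1e-7` relative tolerance
absorbing floating-point ties of the pmf comparison. This is the same rule
R's `fisher.test` uses, and the suite cross-checks agreement on 1000 random
tables as well as exhaustive agreement with a direct enumeration oracle over
a grid of margins up to n = 40. One-sided variants are exposed as an option;
two-sided is the default because the original analyses do not state a
sidedness and two-sided is the conservative convention. A Pearson χ² test
(optional Yates correction, default off) is provided as the asymptotic
companion; no multiple-testing control is applied across hypotheses, since
each invocation decides a single user-stated hypothesis.

On the packaged worked example this yields table (26, 4, 6, 19),
p ≈ 5.1 × 10⁻⁶ (< 0.0001), decision "supported" at alpha 0.01, with
provenance 55 cores / 5 slides / 3 experiments.

## Missing data

Cores missing either the classifier or the dependent value appear in no
cell: the mapping emits no triple for a missing cell, so such cores match
none of the four patterns — a complete-case analysis. Consequently the four
cells sum to the number of distinct cores that carry the shared property and
both factor values, which the suite asserts on datasets with injected
missingness.

## The synthetic-data generator

The generator emulates a multi-experiment TMA study: experiments × slides ×
cores with one sample per core, a diagnosis shared by all samples, one
stained marker, and one clinical attribute. Per core, the joint (classifier
∈ hypothesis set, dependent ∈ hypothesis set) indicator pair is drawn from
the unique 2×2 distribution with the configured marginals and odds ratio
(Plackett construction: the (1,1) cell solves a quadratic in the odds
ratio); the concrete categorical value is then drawn uniformly within the
chosen side's value set. Defaults (p_classifier = 0.58, p_dependent = 0.55,
OR = 20) are the empirical margins and odds ratio of the worked example's
26/4/6/19 table, so default simulations live at the published study's
operating point.

What the generator does **not** emulate — and what passing simulations
therefore cannot certify about real TMA data:

* slide- or experiment-level random effects: cores are assigned round-robin
  and drawn i.i.d., mirroring the pooled-core test, which ignores the
  clustering of cores within patients and slides that real data exhibit;
* inter-observer scoring noise and image-derived intensity artefacts;
* structured missingness (values go missing independently at a flat rate).

Simulation checks computed by the suite and the acceptance script, at these
problem sizes (chosen to estimate each rate with adequate precision while
keeping a full run in minutes): type-I error at OR = 1 with n = 200 cores
(nominal 0.05, observed within ±0.02, 400--1000 replicates); power > 90% at
OR = 20, n = 55, alpha = 0.01 — confirming that a study of the published
size can support p < 0.0001 outcomes; Haldane-corrected empirical OR within
±20% of targets 1, 5 and 20 at n = 5000. Simulation tables are computed by
direct tabular filtering (`contingency_from_dataset()`), whose equality with
the full RDF path is itself asserted on 100 random datasets per run — the
fast path never goes untested.

## Schema and I/O choices

The relational schema is the minimal one the four-way join needs:
`Experiment(Id, Name, ExpType)`, `Block(Id)`,
`Slide(Id, ExperimentId, BlockId, MarkerName)`, `Core(Id, SlideId,
SampleId)`, `SampleAttribute(Id, SampleId, AttributeName, Value)`,
`StainingResult(Id, CoreId, MarkerName, Intensity, Range)`. The two
attribute tables carry a surrogate `Id` so every row has a single-column
primary key to build its subject URI from. The shared condition is matched
as a `Diagnosis` sample attribute. Staining `Range` is modelled for
completeness but participates in no worked hypothesis. Values are compared
case-sensitively after whitespace trimming: these are controlled
vocabularies, not free text.

Datasets travel as one TSV per table (header row, first column the primary
key, empty cell = missing). N-Triples output is one sorted line per triple,
hence byte-deterministic; Turtle output groups triples by subject. The
parser accepts exactly the subset the serializer emits.

## Known limitations

* Cores are the counting unit and are treated as independent; p-values on
  clustered data will be anti-conservative. A mixed-effects or
  patient-level analysis is outside the current scope.
* Only single triadic hypotheses are supported — no conjunctions of triads,
  survival endpoints, or continuous marker values.
* The query evaluator is an in-memory store for analysis-sized datasets, not
  a database: everything is loaded and indexed per session.
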