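---
title: "Semantic integration and cohort selection with cohortkg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic integration and cohort selection with cohortkg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortkg)
```

## The integration model

`cohortkg` treats semantic integration of multi-source study data as three
coupled problems: (1) *harmonization* — different sources store the same
measurement under different column names and conventions; (2) *semantic
instantiation* — harmonized values only become reusable when the entities
they are about (subjects, assays, brain structures, measurements) are
represented explicitly; (3) *selection and analysis* — cohorts are defined
by graph patterns over that representation, not by ad-hoc table filters.

The representation follows the OBO Foundry style. Every subject is an
instance of *Homo sapiens* (NCBITaxon_9606) in which a *study subject role*
(OBI_0000097) inheres (RO_0000052) and which an identifier instance denotes
(IAO_0000219). A completed assessment is an assay instance (for the MoCA,
NPT_0020000) with the subject as participant (BFO_0000057); its result is a
*measurement datum* (IAO_0000109) reached via *has specified output*
(OBI_0000299), which carries a *value specification* (OBI_0001933) via
OBI_0001938, which in turn carries the literal score via *has specified
value* (OBI_0002135). Image-derived features use the same output pattern on
a feature-extraction process with an image (IAO_0000101) as specified input
(OBI_0000293); the volume datum is linked to the subject's hippocampus
instance with *is about* (IAO_0000136). The separation of datum and value
specification looks heavy for a single number, but it is what makes
measurements of the same quality from different instruments and pipelines
co-queryable.

Two modelling choices were genuinely open and are worth recording:

* **Aboutness relation.** The field's standard information-artifact
  aboutness property (IAO_0000136, *is about*) links measurement data to
  the anatomical or cognitive entity measured. Nothing else in the pattern
  depends on this choice; swapping the property requires touching one
  constant.
* **Which cognitive-function instance an assessment measures** is
  configurable (`default_subtest_functions()`): the MoCA total maps to a
  global-cognition function instance and the category-fluency subtest to a
  semantic-fluency function instance, both inhering in the subject's brain.
  The table is data, not code, because subtest-to-function attribution is
  instrument-specific and debatable.

### Application ontology and namespaces

Classes that the core OBO vocabularies do not provide — the anatomy
skeleton, the volumetric feature-extraction processes and their datum
classes, the defined cohort classes — live in the package's application
namespace `https://kg.cohortkg.org/onto/`. IRIs there use readable local
names (`LeftHippocampalVolumeFeatureExtractionFIRST`) rather than opaque
numbering; the package is the only authority for this namespace, so
readability wins. Subject instances are minted under
`https://kg.cohortkg.org/subject/`. Both namespaces are deliberately free
of digits: pseudonym local names are digest-derived strings over the
letters g–v, so a raw subject identifier containing digits can never occur
as a substring of any minted IRI.

Application-ontology terms are defined with `define_term()`, which supports
exactly the axiom shape the instance pattern needs: one or more named
parents plus existential (`some`) restrictions. Universal quantification,
cardinalities and boolean class expressions are out of scope — nothing in
the pipeline consumes them, and restricting the language keeps the module
extractor's closure semantics exact.

### Module extraction

`extract_module()` implements recursive reference closure: the module
contains the seeds, every axiom (triple subtree, following restriction
blank nodes) of each member, and recursively every class or property those
axioms reference. This is intentionally simpler than syntactic-locality
(SLME) extraction: closure is exact, easily testable (monotonicity,
idempotence, identity on full seed sets), and sufficient for the shallow
vendored module shipped in `inst/extdata/core_ontology.ttl`. Loading full
OBI/NPT releases works through the same Turtle reader, but the guarantees
are only as good as closure semantics — a locality-based extractor would be
needed to claim logical completeness against rich ontologies.

## RDF machinery

No RDF or SPARQL library for R is available in this stack, and the triple
container, serialization and query engine are core to the method, so the
package implements them natively:

* Graphs are data frames of `(s, p, o, literal-flag, datatype)` with
  per-triple provenance columns; set semantics make `merge_graphs()`
  idempotent, commutative and associative.
* Turtle and N-Triples are read and written in a restricted but standard
  dialect (prefixes, predicate/object lists, typed literals, blank nodes).
  The N-Triples writer is canonical — sorted, deterministic blank-node
  names — so pipeline determinism is testable as byte equality. The test
  suite cross-checks the Turtle writer against an independent RDF stack
  (Python's rdflib) on a fixture graph.
* The SPARQL engine supports the SPARQL 1.1 subset the cohort template
  needs: SELECT/ASK/CONSTRUCT, basic graph patterns, numeric and string
  FILTER comparisons, DISTINCT and ORDER BY. Instance IRIs are
  deterministic suffixes of the subject IRI, so instance graphs contain no
  blank nodes and graph isomorphism reduces to canonical equality there; a
  blank-node-aware isomorphism check (signature refinement plus
  backtracking) covers ontology graphs with restriction blanks.

Two store-specific behaviours are emulated for portability. The vendor
predicate `sesame:directType` is evaluated virtually as `rdf:type` minus
strict-subclass matches. And the published form of the cohort query filters
an unbound variable (`?val`) while the score binds to `?score`; the engine
gives this standard SPARQL semantics (a type error in FILTER keeps no
solutions), while the package's own `cohort_query()` template treats the
published text as an erratum and filters on the bound `?score` — the
surrounding intent ("subjects that scored below the threshold") is
unambiguous. Both behaviours are under test.

## Harmonization and pseudonymization

A field mapping is a validated `(source, header) → pattern_key` table with
value types and valid ranges drawn from a catalogue. Harmonization is
total-with-report: every header is either mapped or listed as unmapped;
nothing is silently dropped. Cells that fail typing or fall outside the
instrument's valid range (MoCA total outside [0, 30], for example) are
quarantined to an exceptions report and never ingested; missing cells
simply produce no triples, keeping the graph pattern clean. Only the MoCA
total and category-fluency keys ship mapped by default — they are the
measurements the two emulated sources share; other instruments are
admissible pattern keys but aggregation across instruments is out of scope.

Subject pseudonyms are salted MD5 digests (via base R's `tools::md5sum`)
truncated to 96 bits and re-encoded over the letters g–v. The requirements
are determinism, one-wayness in practice, salt separation of pseudonym
spaces, and the no-substring-leak property; any keyed one-way function with
those properties would do. The two synthetic cohorts are assumed disjoint
(no subject appears in both sources), consistent with their being separate
studies; cross-source record linkage is explicitly not attempted.

## The statistical endpoint

Volumes are normalized per subject by total intracranial volume; the
default analysis uses the bilateral hippocampal sum (both sides are
modelled in the graph and "hippocampal volumes" is naturally bilateral),
with `volume = "left"`/`"right"` as alternatives. PD subjects are
stratified at the conventional MoCA impairment threshold (26, strict `<`
for impairment); healthy controls are never split by score even though
some HC subjects score below 26 — the stratification question concerns the
patient group. The omnibus test is a fixed-effects one-way ANOVA computed
from sums of squares, with p from the F distribution on (k−1, N−k) df.
Fisher's LSD runs regardless of omnibus significance and is reported
alongside the omnibus p; its pairwise t statistics use the pooled
within-group mean square and df, unadjusted for multiplicity — that is the
LSD procedure's definition, and its dependence on the omnibus gate is left
to the analyst. p-values come from the classical F and t distributions, not
permutation, matching the named tests.

Degenerate inputs are handled explicitly: zero within-group variance with
unequal means reports F = ∞, p = 0 with a `degenerate` flag; any group with
fewer than two observations is an input error; subjects with missing scores
or volumes are excluded and counted in the result object.

## The synthetic generator as study conditions

`table1_config()` fixes the study conditions: source 1 with 29 PD / 21 HC
and source 2 with 69 PD / 31 HC; group MoCA means 25, 26.6, 26.9, 28.1;
female fractions 0.28 / 0.62 / 0.34 / 0.39; mean ages 67.1 / 69.7 / 61.8 /
58.7 years; mean education 17.9 / 17.1 / 16.4 / 17.2 years; Hoehn–Yahr
means 2.29 / 0 / 1.65 / 0. Only means are available for calibration, so
spreads are package defaults chosen for plausibility: MoCA sd 3 points,
age sd 8 years, education sd 2.5 years, Hoehn–Yahr sd 0.5. No volume
summaries are available at all; the volume priors — hippocampus
N(3700, 400) mm³ per side, ICV N(1.45 × 10⁶, 1.3 × 10⁵) mm³ — are
plausibility choices at the scale of adult subcortical segmentation
output, and are labelled as such rather than calibrated.

MoCA scores are generated as an exact mixture decomposition: the
sub-threshold count per group is fixed first (default
`round(n · P(N(mean, sd) < 25.5))`, overridable to plant counts exactly),
then scores are drawn from the matching truncated normals on either side of
the threshold, rounded and clipped to [0, 30]. Because the two truncated
components with those weights recompose the original normal, sample means
stay calibrated while sub-threshold counts are exact by construction —
which is what makes the end-to-end conservation check (a preset planting
78 + 32 = 110 sub-threshold subjects across the two sources) a meaningful
test of the pipeline rather than of the random number generator. The
planted effect subtracts `delta` (default 0.8) volume standard deviations
from both hippocampi of sub-threshold PD subjects only. Hoehn–Yahr is
emitted as a demographic column and drives nothing downstream.

What the generator does **not** emulate: item-level assessment data,
longitudinal visits, site- or scanner-dependent volume biases, missingness
mechanisms, realistic correlation between cognition and volume beyond the
planted step effect, and value-level dialect differences (both sources use
the same PD/HC group labels; only headers differ). Passing tests therefore
demonstrate the pipeline's correctness — harmonization, graph construction,
query/filter equivalence, statistical calibration — not that real
multi-site data would show any particular effect.

## Numerical and reproducibility choices

* All randomness flows from a single integer seed; the generator saves and
  restores the caller's RNG state.
* SPARQL results without ORDER BY are sorted canonically, and reports are
  ordered by rule then focus node, so all outputs are deterministic.
* The pipeline writes canonical N-Triples; rerunning with the same seed and
  config yields byte-identical graphs, which the tests assert.
* Test and simulation sizes are chosen to exercise the properties at
  meaningful power while staying quick: 50 fuzzed cohorts (5–15 subjects
  per group) for query/oracle equivalence across comparators and
  thresholds, 2000 null replicates for the type-I rate at the three-stratum
  sizes (38/60/52), and 300 generator replicates for planted-effect
  ordering recovery.

## Known limitations

* The SPARQL engine is a subset: no OPTIONAL, UNION, property paths,
  aggregation or named graphs. The cohort template and the package's query
  needs stay inside the subset by design.
* No OWL-DL reasoning or classification: defined classes are materialized
  by rule (SPARQL-definable semantics), which matches threshold-style
  definitions but not arbitrary class expressions.
* Module extraction is reference closure, not locality-based extraction.
* The statistical endpoint is the classical fixed-effects ANOVA chain; no
  covariate adjustment (age, sex, site) is provided, although the
  harmonized table carries the columns an analyst would need for it.
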