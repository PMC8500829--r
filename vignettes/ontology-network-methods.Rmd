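---
title: "Building and evaluating a clinical ontology network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating a clinical ontology network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontonet)
```

## The model

An ontology network represents a clinical domain as a collection of small,
independently maintainable ontology modules connected by *meta-relations*:
object properties whose domain and range classes live in different modules
and which carry the network's own namespace
(`http://www.diabetes-mexico.org/red#`). The diabetes network built here has
six domain modules built from scratch — Person, Clinical Entity, Clinical
Information Administration, Education Level, Geographic Location, Control
Plan — plus a reused Drug/ATC module, 14 meta-relations (9 selected at the
design stage, 5 added when non-ontological resources were integrated), and a
network-level Prescription Dose class.

Prescription Dose deserves a note: it belongs to no single module, because a
dose is meaningful only as the join of a medical note (Clinical Information)
and an active ingredient (Drug/ATC). It is therefore declared in the network
namespace itself (`red:Dosis_En_Receta`), and meta-relations touching it are
exempt from the otherwise enforced cross-module rule.

Several classes are *non-primitive*: defined by a conjunction of property
restrictions rather than by assertion alone. A Patient, for instance, must
have exactly one residence, one education level, one clinical record, one
birth date and one sex; a Medical Note must carry its full panel of signs,
exactly one author, at least one diagnosis and at least one prescribed dose.
These contracts drive the consistency checker.

### Naming

The network mixes two naming conventions by construction: the executable
queries use Spanish local names (`tienePeso`, `tieneExpedienteClinico`,
`resideEn`) while the design documentation uses English verb phrases
(`hasWeight`, `hasClinicalRecord`, `livesIn`). We store Spanish local names
as canonical — they are what the competency queries must resolve — and
attach the English names as `rdfs:label`; `name_aliases()` maps either
spelling to the canonical one, so rule files and registries may use both.
One quirk is handled here: the design table spells one relation
"hasTreatmento"; both it and `hasTreatment` alias to `tieneTratamiento`.
Clinical-entity individuals use CamelCase (`DiabetesMellitusTipo2`, as the
queries expect); drugs, states and education levels use underscore slugs
(`Insulina_Lispro`, `Baja_California`).

### Fixtures the documentation does not enumerate

The Education Level module is documented as holding 13 individuals but the
levels are not listed anywhere; `education_levels()` ships a 13-level
Mexican academic scale (Ninguno through Doctorado, grouped into basic,
upper-secondary and higher education) explicitly marked as a fixture, so the
count is testable without silently inventing content. The gazetteers under
`inst/extdata/gazetteers/` (diseases with ICD-10 codes, symptoms, signs,
anatomy, active ingredients with ATC codes) and the ATC branch of the
Drug-ATC demo module are likewise synthetic fixtures standing in for the
clinical vocabularies and the national drug catalogue, which are not
distributable.

## The rule engine

Rules are Horn clauses over class atoms, property atoms and builtins
(`multiply`, `divide`, `add`, `subtract`, `greaterThanOrEqual`, `lessThan`,
`greaterThan`, `lessThanOrEqual`, `stringEqualIgnoreCase`). Heads are
property atoms only, and rules must be DL-safe: every head variable occurs
in the body. The engine runs forward to fixpoint; since rules only add
triples and matching is set-based, the fixpoint is unique — shuffling rule
or fact order cannot change the result, which the test suite verifies under
seeded shuffles.

Unit conventions, inferred from the formulas' magnitudes and documented as
package policy: weight in kg, height in m, waist and hip in cm (their ratio
is unitless), age in whole years, BMR in kcal. The default rule set contains
exactly the documented behaviour — the Overweight band `[25, 30)` kg/m² and
the basal-metabolic-rate variant for women aged 61 and over
(`10.5 kcal/kg · weight + 596 kcal`). Other biotype bands and BMR strata are
extension slots (`biotype_bands()`, `bmr_variants()`) shipped disabled, so
the default observable behaviour is precisely the documented one.

Numerically, builtin comparisons are exact IEEE-double comparisons (as rule
engines' are); derived-value equality in tests uses an absolute tolerance of
1e-9. Derived literals are formatted to 15 significant digits, giving one
canonical string per value so that re-derivation never duplicates a triple.

## Population and the synthetic corpus

`populate()` converts structured clinical records into individuals using
deterministic slugs from record ids (`Paciente_P001`, `Expediente_P001`,
`Nota_P001_2`, dose nodes `_bnDosis_P001_2_1`), so re-population is
idempotent and serialization reproducible. Each module's IRI hosts its own
entities; meta-relation assertions use the network IRI. The age on each note
is the floor of the year difference between birth date and note date,
because the BMR rule traverses the note, not the patient sheet.

The generator (`generate_corpus()`) emulates the documented corpus profile:
171 records, 90 male / 81 female patients, 729 diagnoses (143
insulin-dependent DM, 149 non-insulin-dependent DM, 437 other), 1626
prescriptions with Insulin Glargine 131, Metformin 61, Diosmin-with-
Hesperidin 58, remainder spread evenly over a 12-drug fixture list. Totals
are dealt from exact-quota decks rather than sampled i.i.d., so every seed
reproduces the margins exactly; randomness only permutes assignment across
patients and notes. Design choices made once and documented here:

- *Notes per record* is unconstrained by the source profile; the default is
  uniform on 1–4, chosen so that the worst case (4 × 171 = 684 notes) still
  allows one diagnosis and one prescription per note (729 and 1626
  available). The profile validator rejects infeasible combinations before
  generation.
- Every note receives at least one diagnosis and one prescription first;
  surplus deck entries go to uniformly chosen notes. This satisfies the
  Medical Note contract (`hasDiagnosis min 1`, `hasTreatment some`).
- Sign values are drawn from plausible adult ranges (weight 45–120 kg,
  height 1.40–1.95 m, glucose 70–300 mg/dl, waist 60–140 cm, hip 70–150 cm,
  ages 25–90).
- Sex is stored as `"Male"` / `"Female"` because the BMR rule compares the
  literal `"Female"` case-insensitively; a Spanish value would silently
  disable the rule.
- Each record's history lists at least one disability, because the Clinical
  History class is defined by `hasDisability some Disability` and the
  end-to-end consistency check would otherwise flag every history. This is
  a corpus-design convenience, not a clinical prevalence claim.
- Doctors come from a 12-member roster assigned per note, giving every note
  exactly one author and every doctor at least one note.

What the corpus does *not* emulate: disease co-occurrence structure,
longitudinal sign trajectories, free-text variety beyond templated
narratives, and real gazetteer coverage (the shipped symptom list is small).
Passing tests on this corpus therefore demonstrate the mechanics of the
pipeline — exact bookkeeping, contract satisfaction, rule correctness —
not extraction recall on real clinical Spanish.

## Extraction

Tagging is gazetteer-based: tokens are folded by NFD decomposition with
combining marks removed (so `hipertensión` matches `HIPERTENSION`), and
gazetteer hits take the longest match first, never overlapping. Every token
also gets a shallow part-of-speech tag from a small closed-class Spanish
lexicon (everything unknown is a Noun; numerals are Num). Nominal phrases
follow the swappable shallow pattern `Noun (Adj | "de" Noun)*` over tokens
not already covered by a semantic term.

Triplet formation applies per-tag patterns: disease and symptom lists
anchor to the medical note (`presentaEnfermedad` / `presentaSintoma`); a
sign term immediately followed by a number proposes a data property
`tiene` + SignName typed float when the value parses as a number, else
string; NominalPhrase–Verb–NominalPhrase sequences propose generic
relations. The interactive review screen is replaced by a deterministic
file round trip (emit → edit → apply) preserving register / skip / edit
semantics; skipped candidates provably never change the network.

The integration flow routes accepted triples: absent endpoints are created
as individuals of the owning module's master class — refined to the
relation's declared domain/range class when the relation already exists, so
assertions always land inside declared signatures — then re-verified; new
object properties always take the network namespace, new data properties
the Clinical Information Administration namespace.

## Evaluation

Competency questions are SPARQL queries with expected result shapes. The
supported SPARQL subset is basic graph patterns, `SELECT [DISTINCT]` and
simple `FILTER` comparisons — sufficient for the registry, and documented
as a subset. Queries run over the full triple view with `sameAs` pairs
expanded (a query-layer equivalence, not OWL reasoning: cheap, decidable,
and all the catalogue linking needs).

The cardinality checker compares observed per-individual property counts
against the class contracts. Restrictions over rule-derived values
(`tieneIMC`, `tieneICC`, `tieneTMB`, `tieneBiotipoHumano`) are checked as
upper bounds only: under open-world semantics a missing derived value is
never a contradiction (the BMR rule lawfully covers only women 61+), while
a duplicated "exactly 1" value is a real fault either way. Asserted-property
restrictions are checked closed-world in both directions, so a doctor with
no notes or a patient with two residences is flagged. The lint pass mirrors
a pitfall scan: missing `rdfs:label`/`rdfs:comment` metadata,
naming-convention mixing, and absent inverses — the latter informational
only, since the network omits inverses deliberately to keep reasoning cheap.

## Serialization

Turtle is the canonical on-disk form: one file per module plus
`network.ttl` importing all, one triple per line, subjects sorted, then
predicates, IRIs before literals, so two writes of the same network are
byte-identical and the parse/serialize round trip is exact. Restriction
conjunctions are serialized as structured annotation literals
(`red:tieneRestriccion "property|kind|n|filler|derived"`) rather than OWL
blank-node syntax; this keeps the subset line-oriented and the round trip
lossless, at the cost of OWL-tool interoperability for that one construct.
Blank-ish nodes (dose and mapper nodes) get stable generated names with the
reserved `_bn` prefix, so serialization never depends on memory addresses.

## Problem sizes and limitations

The test suite exercises a 10-record corpus for module tests and the full
171-record corpus for the generator margins and the end-to-end pipeline
(schema → corpus → populate → extract → derive → evaluate), which completes
in about a minute on one CPU. Known limitations: no OWL-DL reasoning (no
property chains, negation, or tableau consistency — the internal checker is
deliberately closed-world and cardinality-only), no dependency parsing or
negation detection in extraction, no unit conversion for dose amounts, and
Turtle fidelity is guaranteed only for the documented subset.
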