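---
title: "kbmatch: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kbmatch: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbmatch)
```

# The problem

Clinical variant knowledgebases curate statements of the form "variant V
in gene G predicts response to drug D in disease X, at evidence level L".
Interpreting a sequenced tumor means joining its observed variants against
those curated records. `kbmatch` implements that join offline: a linked
record model over snapshot files, a local cache, a coordinate-matching
engine, a VCF exporter, and a cohort summarizer — plus a synthetic
generator so every component is testable with known ground truth and no
network.

# The record model

Eight entity types carry persistent public identifiers and can be cached:
gene, variant, variant group, evidence, assertion, source, user,
organization. Evidence items grade clinical significance by level —
A (validated), B (clinical), C (case study), D (preclinical),
E (inferential) — and move through a review lifecycle of `submitted`,
`accepted`, or `rejected`. Composite payloads without identifiers
(diseases, drugs) are attribute blobs: attached to records, never cached
standalone. Drugs/diseases as first-class records are deliberately out of
scope here.

Records are R environments, so `resolve_links()` can materialize links as
*shared* instances: two evidence items citing the same source hold the
identical object, and chains variant → evidence → source → … never copy.
A link to an id absent from the snapshot resolves to a *partial record*
carrying only `(type, id)`; this is logged, never an error, because public
snapshots legitimately contain dangling references. Partial records are
equivalent to their full counterparts for caching purposes: both map to
the same `record_key()`.

Status filtering (`filter_by_status()`) defaults to
`accepted + submitted`: rejected material is retained in snapshots for
provenance but is rarely wanted downstream. The filtered collection
shares evidence/assertion/source objects with its input and rebuilds only
the variant/gene shells, so the input is never mutated.

## Snapshot dialect

The snapshot is one JSON document with one top-level array per entity
type (schema in `inst/extdata/snapshot-schema.json`; plain or gzipped).
A single-file atomic snapshot mirrors a nightly-dump distribution model
and keeps `refresh_cache()` trivially atomic (write-temp-then-rename).
No pre-installed R jsonschema validator exists, so the parser enforces
the schema structurally itself: unknown sections, duplicate ids, and
enum violations (status, level) are errors naming the offender.

# Caching

`record_key()` concatenates a per-session random salt with `(type, id)`.
This reproduces, in R, the observable behaviour of per-session string
hashing: keys are stable within a session, deliberately unstable across
sessions, and never persisted — the on-disk cache is the snapshot JSON
plus a small header (`built_at`, `expiry_days`, format version), keyed
only by `(type, id)`, with session keys recomputed on load. The cache is
human-inspectable by design; an opaque binary serialization would be
faster but harder to audit and version.

Expiration: a cache is stale iff `now − built_at > expiry_days`, default
7 days. The boundary is inclusive of validity (exactly 7 days old is
still fresh); the upstream description gives no boundary semantics, so we
fixed one and test it strictly on both sides. Staleness is monotone in
`now` (property-tested).

# Coordinate search

## The index

`build_index()` extracts one row per usable coordinate set:
`(chromosome, start, stop, alt, variant_key)`, 1-based fully-closed
intervals on GRCh37. Compound variants (fusions, two coordinate sets)
contribute two rows sharing one variant reference; variants missing
chromosome/start/stop contribute none and are counted in the build
report. Rows sort by chromosome (natural order 1–22, X, Y, MT, then
other labels lexicographically), start, stop, alternate sequence, with
variant id as a deterministic tie-break.

## Match modes

With closed intervals, for query q and entry e on the same chromosome:

* `any`: `q.start ≤ e.stop ∧ e.start ≤ q.stop`
* `query_encompassing`: `e.start ≥ q.start ∧ e.stop ≤ q.stop`
* `record_encompassing`: `q.start ≥ e.start ∧ q.stop ≤ e.stop`
* `exact`: equal start and stop, and alt-compatible — a missing or `"*"`
  query allele is a wildcard; otherwise the alleles must be equal.

Range modes are defined purely on coordinates; only `exact` consults the
allele. These definitions imply the nesting
`exact ⊆ QE ∩ RE ⊆ any`, which the test suite asserts on every random
instance rather than assuming.

## The two-pointer merge

Queries are sorted by the index ordering. Per chromosome, a permanent
pointer advances past entries whose `stop` lies strictly before the
current query's `start` — safe because later queries start no earlier, so
such entries can never match again. The candidate window then runs to the
last entry whose `start` does not exceed the query's `stop` (located by
binary search on the start-sorted slice; this replaces a linear walk
without changing the scanned set or the restore semantics), the mode
predicate is evaluated inside the window only, and the pointer is
restored for the next query. The scan bound `e.start ≤ q.stop` is the
minimal correct bound when entries are start-sorted but have
heterogeneous stops: the adversarial case — one enormous interval ahead
of many short ones — is exactly what the permanent-advance rule must not
discard, and it has a dedicated fixture.

Work is O(|index| + |queries| + scanned pairs). We do not benchmark wall
time (hardware-dependent); instead `bulk_search()` counts pointer
advances plus predicate evaluations, and an acceptance test checks the
count at n = m ∈ {1000, 2000, 4000, 8000} under fixed overlap density,
requiring every doubling ratio ≤ 2.2. Correctness is never argued from
the algorithm: every acceptance run compares against a brute-force
all-pairs oracle implemented independently in the tests.

Matched variants are de-duplicated per query (a fusion matching on both
split rows reports once) and returned in the original input order with
ids sorted ascending for determinism.

# VCF export

One VCF 4.2 record per exportable variant; co-located variants are never
merged, and duplicate `add_record()` calls are not de-duplicated (no
upstream rule exists; documented instead of invented). Exportability:
chromosome and start present, no second coordinate set, and alleles in
one of three shapes — both (SNV/complex), alt only (insertion), ref only
(deletion). Everything else is skipped with a warning, never an error.

Without a reference FASTA, VCF's non-empty-allele rule needs a dialect
for pure indels: insertions emit `REF="N"`, `ALT="N"+alt` at start;
deletions emit `REF="N"+ref`, `ALT="N"` at start−1. This is documented
here and flagged in the header `source` line; consumers needing
left-anchored alleles against a real genome must re-normalize.

Each status-passing evidence item and assertion becomes one `CSQ` entry
(evidence first, then assertions, ascending id), pipe-delimited over the
fields of `csq_fields()`, with `KB_Entity_Type` discriminating the two.
Values are escaped reversibly: spaces → `_`; every other byte outside
`[A-Za-z0-9.:/-]` — including literal underscores, so decoding is exact —
becomes uppercase `%XX` over UTF-8 bytes. Multi-valued fields join with
`&` after escaping. The inverse (`decode_csq_value()`) is property-tested
on random strings; emitted values can never contain VCF-reserved
characters.

# Cohort analysis

The MAF-like input uses the standard column names
(`Tumor_Sample_Barcode`, `Chromosome`, `Start_Position`, `End_Position`,
`Reference_Allele`, `Tumor_Seq_Allele2`); `-`, `.` and empty strings are
absent-allele spellings. Each row becomes a query tagged with its
barcode; exact-mode queries carry the tumor allele.

Sample classification is a strict partition: `exact` (≥ 1 exact-matched
variant) ≻ `any_only` ≻ `none` ≻ `no_variants`. The highest evidence
level is summarized over exact matches only — an overlap-only match is
too weak a claim to inherit a level — taking the maximum under
A > B > C > D > E across status-passing evidence of all exact-matched
variants. An exact-matched sample whose matched variants carry no
status-passing leveled evidence reports `NA`; the cohort report gives
that its own bucket so level fractions still partition the exact class.

# The synthetic world

The generator states one fixed world; its defaults are not tuned:

* `variants_per_sample_mean = 6.88` — the reported cohort average.
* `planted_exact_fraction = 0.076`, `planted_overlap_fraction = 0.429` —
  the reported variant-level exact and additional any-overlap match
  rates.
* `fraction_empty_samples = 0.087` — the reported fraction of tumors with
  no variants. Because Poisson(6.88) alone would make empty samples
  vanishingly rare, empties are drawn as a separate fraction and the
  remaining samples use the Poisson; the overall mean is therefore
  slightly below 6.88, a documented approximation.
* Entity counts (25 genes, 300 variants, 600 evidence, 30 assertions),
  `fraction_compound = 0.10`, `fraction_missing_coords = 0.05`, status
  weights (0.60/0.25/0.15) and level weights
  (A 0.05, B 0.30, C 0.30, D 0.25, E 0.10) are stated nowhere upstream;
  they were chosen once as plausible for a mid-sized curated knowledgebase
  and are not revisited. All are configurable.

Coordinates live on a simulated genome of 5 chromosomes × 1 Mb so overlap
densities stay controllable. Knowledgebase variants occupy positions up
to 700 kb; planted `none` rows draw from 800–999 kb, a region disjoint
from every knowledgebase interval, so a `none` label is guaranteed by
construction. `overlap` rows take a knowledgebase interval and expand it
by 1–50 bases on at least one side (always overlapping, and re-drawn if
the expanded interval coincides with any knowledgebase interval, so never
exact). `exact` rows copy coordinates and allele verbatim. Truth labels
are therefore consistent with the search predicates by construction, and
a test verifies that the real search reproduces them exactly.

What a green test does **not** establish: the generator has uniform
positions, no mutation spectrum, no gene structure, no recurrent hotspot
skew, and its per-row match planting is independent across rows — real
tumor cohorts violate all of these. Green here means the machinery is
correct, not that real-cohort match percentages would be reproduced.

# Numerical and degenerate-input choices

* Chromosome labels are normalized (`chr` stripped, `M` → `MT`); unknown
  labels are kept and sort after the canonical set, lexicographically.
* `NA` alternate sequences sort first within equal coordinates; ties
  break on variant id, so index builds are reproducible.
* Empty query lists, empty indexes and empty snapshots are identities,
  not errors; `start > stop` is always an error at construction time.
* Seeded generation saves and restores the caller's RNG state.
* The expiry boundary, the `%XX` escape set, and the indel dialect are
  fixed choices where upstream behaviour is undocumented; each is tested
  on both sides of its boundary.

# Known limitations

* Fusions export to the index (two rows) but not to VCF — an explicit
  upstream limitation we preserve.
* No liftover: queries must carry the index's build label, and GRCh37 is
  the only label the generator emits.
* No HGVS or transcript-coordinate matching; matching is purely genomic.
* The live-service client is out of scope; `refresh_cache()` abstracts a
  snapshot source as a path/URL and the tests exercise local files only.
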