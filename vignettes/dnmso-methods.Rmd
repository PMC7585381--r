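---
title: "The dnmso document model: design, validation and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dnmso document model: design, validation and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnmso)
```

## Why an ontology-shaped container

A de novo peptide-spectrum match is not tree-shaped data. One prediction
may be supported by several spectra (CID and ETD scans of one precursor,
or merged spectra), and one spectrum usually carries several ranked
candidates — a many-to-many network that XML containers model awkwardly.
`dnmso` therefore treats a result set as a graph: the in-memory document
maps one-to-one onto an RDF triple set, and Turtle, RDF/XML and JSON-LD are
three textual views of the same triples. Everything else in the package —
validation, filtering, SPARQL, consensus — operates on that one model.

The model deliberately excludes sample handling and experiment metadata
(that belongs to acquisition standards like mzML), protein inference and
database information: de novo sequencing has no database to describe, which
is exactly why database-search formats fit it badly.

## The sequence model and mass arithmetic

A predicted sequence is an ordered run of three element kinds:

* a plain amino acid (the 20-letter alphabet; `U`/`O` are rejected),
* a modified amino acid — *reducible* to its plain residue, plus a
  reference to a modification entry, and
* a mass gap, the standard way to write a stretch a tool could not resolve
  into residues.

Masses are monoisotopic Daltons throughout, because that is what de novo
tools operate on; gap masses are likewise monoisotopic (the average-mass
alternative would be inconsistent with fragment arithmetic). The neutral
peptide mass is the element sum plus one water (18.010565 Da); charge
enters only when comparing to a precursor, via
`neutral = (m/z − 1.007276) × z`. Residue masses are frozen from elemental
compositions at six decimals; the test suite re-derives them from atomic
masses as an independent oracle. Two invariants pin the arithmetic down:

* *additivity* — concatenating sequences adds masses minus one water per
  joint, and
* *gap closure* — replacing any residue run by a gap of exactly its summed
  mass leaves the total unchanged to 1e-9 relative tolerance. This is also
  the internal-consistency check between the synthetic generator's
  precursors and `sequence_mono_mass()`.

Every modification must reference a PSI-MOD accession (`MOD:` + five
digits) *and* carry its own mass deltas, so a document remains
interpretable without the ontology at hand. The bundled table is a small
curated subset written in PSI-MOD conventions (a synthetic excerpt, not the
ontology itself); `read_psimod_obo()` ingests the real file when the user
has one. Rendering uses two styles: plain (`"G(100.00000)A"`, gaps to five
decimals, modifications dropped) and annotated (`"S[MOD:00046]"`);
stripping annotations from the annotated form always yields the plain form,
and parsing inverts rendering (gap masses are accepted at any precision, so
only the 5-decimal rounding is lost).

## Validation: rules instead of a reasoner

OWL reasoning would make validity depend on an external classifier. The
package instead enumerates the model's structural invariants as
deterministic rules; `validate_document()` returns a tibble of violations
ordered by offending element and never throws. Severities split into ERROR
for format-mandated constraints — a prediction without source spectra or
without a score, a dangling reference, a modification without a PSI-MOD
accession, unsorted or negative peaks, duplicate local ids — and WARNING
for advisory findings (empty provenance, unregistered CV references,
dangling software references). Serializers refuse documents with ERROR
violations; deserializers load anything structurally parseable and leave
judgement to the validator, so a hand-written file with an orphan
prediction is read and then reported, not rejected at parse time.

Construction is guarded (`add_spectrum()`/`add_prediction()` enforce the
same invariants at insertion), which yields the tested equivalence: any
document built through the guarded API validates clean, and each
single-defect mutation from the test catalogue is flagged with its rule.

Two deliberate asymmetries: file readers *normalize* unsorted peak lists
(legacy files are messy) while the construction API *rejects* them (new
code should be clean); and an unknown precursor charge is represented
explicitly as unknown, never guessed from context.

## Serialization choices

* Instance IRIs are derived from local ids (`urn:dnmso:<doc>/spectrum/<id>`,
  percent-encoded), so addressable entities never sit on blank nodes and
  output is reproducible; blank nodes occur only as RDF list cells with
  counter-based labels. Serializing the same document twice is
  byte-identical.
* Ordered collections (spectra, predictions, sequence elements, scores,
  source spectra) are RDF lists, which is what guarantees order-exact
  round-trip; repeated properties would not.
* Inline peak lists are a single CSV literal per spectrum, one
  `mz,intensity` row per peak, printed at shortest-exact precision (17
  significant digits when needed) so values round-trip bit-exactly. This
  both keeps files compact and makes the self-containment property
  checkable as `identical()` on doubles.
* Triples outside the package's namespace are carried opaquely and
  re-emitted, giving third parties an extension point without schema
  changes. An instance using a different namespace *version* raises a
  version error instead of being silently misread.
* The vocabulary is versioned under `https://w3id.org/dnmso/1.0#` and
  documented in `inst/extdata/dnmso.ttl`. The SPARQL engine implements
  SELECT over basic graph patterns (PREFIX, DISTINCT, joins on shared
  variables) — enough for navigation and consensus-style queries; OPTIONAL,
  FILTER and property paths are out of scope.

## Converters and their dialects

Flat-text de novo outputs vary by tool version, and no single authoritative
layout exists. Each shipped dialect (PepNovo-style blocks with
`RnkScr`/`PnvScr` columns and N-/C-gap masses; Lutefisk-style sections with
`Pr(c)`/`Quality` and bracketed gaps; the DNML XML predecessor with one
score per prediction; pepXML `spectrum_query`/`search_hit` with
`mod_aminoacid_mass` total residue masses; a PEAKS-style CSV export) is
frozen by the generator in this package, and the parsers reject other
layouts loudly with a dialect hint rather than guessing.

Common converter policy:

* records are matched to companion spectra by title/native id first, then
  scan index, then precursor m/z within 0.01 Th; first match wins;
* converters never emit orphan predictions — an unmatchable record is
  skipped and counted in the `ConversionReport`
  (`converted + skipped = seen` is an invariant);
* residue mass offsets are matched to the modification table at 0.01 Da
  (monoisotopic), preferring residue-specific terms, then generic terms; an
  unmatched offset becomes an explicit `MOD:00000` placeholder with a
  warning, never a silent drop;
* protein/database fields are ignored with a lossiness note.

The mzIdentML exporter is write-only and lossy by design: one
`SpectrumIdentificationResult` per spectrum with predictions and one
`SpectrumIdentificationItem` per prediction (a multi-spectrum prediction is
homed at its first source; the rest are recorded in a userParam), scores as
cvParam/userParam entries, and the gap-bearing plain rendering plus
per-element confidences only as userParams, since mzIdentML peptide
sequences cannot express either. There is no mzIdentML importer.

## Filtering and consensus

Score filtering supports the five comparators (greater, lesser, equal and
the two non-strict forms) over named scores, combined with all/any. A
prediction lacking the named score *fails* the constraint — the
conservative reading. Filtering keeps every spectrum (orphan spectra are
legal; orphan predictions are not), which makes it idempotent and
validity-preserving.

Consensus is defined concretely here (queries alone underdetermine it):
per matched spectrum, take each tool's candidates up to `max_rank`
(default 1), group them into equivalence classes, and emit one consensus
prediction when the largest class covers at least `min_agreement` tools.
Equivalence is strict elementwise equality by default, with two options
reflecting mass-spectrometric reality: I/L collapsing (isobaric residues,
indistinguishable from fragment masses) and gap-aware matching (a gap
matches a residue run whose summed mass lies within `gap_tolerance_da`,
default 0.01 Da). Ties between equally large classes break toward the
earliest-appearing candidate (first tool, best rank). The consensus
prediction carries `agreement_count` and `mean_normalized_rank` (mean of
1/rank over the agreeing candidates), is attributed to a
`dnmso-consensus` software entry, and the output is a valid document like
any other. The agreement strategy is a plain R function and can be swapped
by operating on the per-spectrum report.

K/Q (0.036 Da apart) are *not* collapsed anywhere: at typical MS/MS
accuracy they are distinguishable in principle, and conflating them is an
analysis decision, not a format property.

## What the synthetic generator emulates — and what it does not

`generate_ground_truth()` draws peptides of length 7–12 uniformly from the
20-letter alphabet, modifies a residue-compatible position with probability
0.2 (a realistic order of magnitude for enriched samples, and enough to
exercise every modification path), computes singly protonated b/y ladders,
adds an equal number of uniform-random noise peaks with log-uniform
intensities, and sets the precursor to the doubly protonated peptide.
`write_tool_outputs()` renders the same truth through every dialect;
`agreement_profile` controls the fraction of spectra where all simulated
tools report the truth at rank 1, the rest receiving tool-distinct
single-substitution variants (never I↔L, so strict and I/L modes genuinely
differ). Lower-ranked candidates add substitutions and, in dialects that
can express them, terminal gap replacements with probability 0.2.

This emulates the *structure* of multi-tool de novo output, not its
physics: no fragmentation intensity model, no isotope envelopes, no missing
fragments, no decoys, and noise that is uniform rather than
chemically correlated. Passing tests therefore demonstrate that the
format, converters and consensus machinery are correct and lossless where
promised — not that any scoring or sequencing algorithm performs well on
real spectra (none is implemented).

Test problem sizes are the package's choices for thorough-but-quick runs:
100 random documents (up to 50 spectra and 200 predictions each) through
all three dialects for round-trip fidelity, 1,000 random spectra for CSV
bit-exactness, 500 peptides for mass consistency, 20 spectra × 3 candidates
per dialect for converter conservation, and 100 documents × 5 constraint
sets for the filtering oracle.

## Known limitations

* The SPARQL engine is SELECT/BGP only; hand the serialized Turtle to a
  full triple store for anything richer.
* mzML/mzXML reading covers centroided peak lists (32/64-bit floats,
  optional zlib) on MS2 scans; vendor formats, MS1 handling and
  profile/centroid distinctions are out of scope, as are dta/pkl readers.
* The bundled PSI-MOD subset is a convenience excerpt; serious modification
  work should load the real OBO file.
* Documents live in memory; the package targets result sets, not
  proteome-scale archives.
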