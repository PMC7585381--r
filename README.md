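# dnmso

An ontology-backed container format — with a full R toolchain — for **de
novo peptide sequencing results** from tandem mass spectrometry.

De novo sequencing infers a peptide's amino-acid sequence directly from its
MS/MS fragment spectrum, without a protein database. Unlike database search
(whose results have a community standard, mzIdentML), every de novo tool
writes its own ad hoc output, which blocks downstream integration — in
particular ensemble/consensus analyses that combine several tools. `dnmso`
implements an interchange format for these results as an RDF graph, plus
everything needed to work with it: readers for spectra, converters from
legacy tool outputs, validation, filtering, SPARQL queries, consensus
building and a lossy mzIdentML exporter.

## The data model

A **document** is the root container. It holds:

* **Spectra** — one MS/MS scan each, either *inline* (the peak list as a
  bit-exact CSV literal, `mz,intensity` per line) or as a *reference* into
  an external peak-list file (mzML/mzXML/MGF path + native scan id).
  A document whose prediction-referenced spectra are all inline is
  **self-contained**: it can be shared without the raw data.
* **Predictions** — one peptide-spectrum-match candidate each: a sequence,
  **at least one score** (tools like Lutefisk report several; all are kept,
  named), and **at least one source spectrum**. The prediction–spectrum
  relationship is many-to-many: one prediction may be backed by several
  scans (e.g. CID and ETD spectra of the same precursor, or PepNovo+-style
  merged spectra), and one scan may back many predictions. Predictions
  without spectra are invalid; spectra without predictions are fine.
* **Sequences** — ordered runs of three element kinds: a plain amino acid,
  a modified amino acid (which *reduces to* its amino acid plus a
  modification reference), and a **mass gap** — an unexplained stretch
  given only by its monoisotopic mass, rendered as `"G(100.00000)A"`.
  Each element can carry a confidence in [0, 1] and supporting-peak
  evidence.
* **Modifications** — every PTM must reference a PSI-MOD term
  (`MOD:\d{5}`) and records its own monoisotopic and average mass deltas,
  so instances are interpretable standalone. A curated subset table ships
  with the package; a full PSI-MOD OBO file can be loaded.
* **Software entries and CV sources** — provenance and controlled
  vocabulary (cvParam) annotation.

Documents serialize deterministically to Turtle (default), RDF/XML and
JSON-LD; ordered collections are RDF lists, so element order, score order
and peak order survive round-trip exactly, and triples in foreign
namespaces are preserved opaquely (extensibility). A rule-based
`validate_document()` replaces OWL reasoning: every structural invariant is
checked deterministically and reported as a tibble of violations.

## Worked example

Simulate three de novo tools over the same four spectra, convert each
tool's native output, filter, and build a consensus:

```r
library(dnmso)

fx    <- fixture_spec(seed = 42, n_spectra = 4, n_tools = 3)
truth <- generate_ground_truth(fx)
paths <- write_tool_outputs(truth, fx, tempdir())

pepnovo <- convert_pepnovo(paths$pepnovo, paths$mgf)
pepnovo$report
#> <conversion report> 4 spectra read; 12 records: 12 converted, 0 skipped

head(tidy(pepnovo$document), 4)
#> # A tibble: 4 x 7
#>   prediction sequence  rank n_spectra source_spectra   score_RnkScr score_PnvScr
#>   <chr>      <chr>    <int>     <int> <chr>                   <dbl>        <dbl>
#> 1 PRED_1     VGNPRFM      1         1 synthetic_scan_.        0.907         90.7
#> 2 PRED_2     VGNPRTM      2         1 synthetic_scan_.        0.707         70.7
#> 3 PRED_3     VGNQRFM      3         1 synthetic_scan_.        0.507         50.7
#> 4 PRED_4     KVPARSFR     1         1 synthetic_scan_.        0.819         81.9
```

Each row is one PSM candidate; `RnkScr`/`PnvScr` are the tool's two scores,
kept as distinct named scores. Filtering takes `name op threshold`
expressions with `>`, `<`, `=`, `>=`, `<=` and keeps all spectra (so the
result is still a valid document):

```r
doc <- filter_predictions(pepnovo$document, "RnkScr>=0.5")
length(doc$predictions)
#> [1] 10
```

Consensus across the three tools (top-ranked candidates, at least two tools
agreeing; `--il-equivalent` style I/L collapsing and gap-aware matching are
options):

```r
docs <- list(pepnovo$document,
             convert_lutefisk(paths$lutefisk, paths$mgf)$document,
             convert_dnml(paths$dnml)$document)
cons <- consensus(docs, consensus_params(min_agreement = 2))
tidy(cons)
#> # A tibble: 4 x 7
#>   prediction sequence     rank n_spectra source_spectra    score_agreement_count
#> 1 PRED_1     VGNPRFM         1         1 synthetic_scan_0.                     3
#> 2 PRED_2     KVPARSFR        1         1 synthetic_scan_0.                     3
#> 3 PRED_3     PPCNRKYHFQI     1         1 synthetic_scan_0.                     3
#> 4 PRED_4     QIGAADEAAN      1         1 synthetic_scan_0.                     3
```

All three tools agreed on every spectrum (`agreement_count = 3`), and each
consensus prediction carries `mean_normalized_rank` (mean of 1/rank over
the agreeing candidates). The consensus is itself a valid document: write
it, query it, or export it.

```r
write_dnmso(cons, "consensus.ttl")          # deterministic Turtle
run_query(cons, "SELECT ?name ?value WHERE {
  ?sc a dnmso:Score . ?sc dnmso:scoreName ?name . ?sc dnmso:scoreValue ?value }")
#> # A tibble: 8 x 2  (agreement_count / mean_normalized_rank per prediction)
writeLines(export_mzidentml(cons), "consensus.mzid")   # lossy, write-only
```

A thin command-line wrapper with the same operations (convert, validate,
filter, consensus, export, query, spectra stats, fixtures) is installed at
`system.file("cli", "dnmso.R", package = "dnmso")`.

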