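# DNMSO vocabulary, version 1.0 — terms used by the serializer.
@prefix dnmso: <https://w3id.org/dnmso/1.0#> .
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .

<https://w3id.org/dnmso/1.0> a owl:Ontology ;
    rdfs:comment "Vocabulary for de novo tandem-MS sequencing results: documents, spectra, predictions, sequences of amino acids / modified amino acids / mass gaps, multiple scores, PSI-MOD referenced modifications. Ordered collections are RDF lists; inline peak lists are CSV literals." ;
    owl:versionInfo "1.0" .

dnmso:Document a rdfs:Class ; rdfs:comment "Root container: spectra, predictions, modifications, software, CV registry, provenance." .
dnmso:Spectrum a rdfs:Class ; rdfs:comment "One MS/MS scan, inline (CSV peaks) or externally referenced." .
dnmso:ExternalSpectrumRef a rdfs:Class .
dnmso:Prediction a rdfs:Class ; rdfs:comment "One PSM candidate: a sequence, >=1 score, >=1 source spectrum (many-to-many with Spectrum)." .
dnmso:Sequence a rdfs:Class .
dnmso:AminoAcid a rdfs:Class .
dnmso:ModifiedAminoAcid a rdfs:Class ; rdfs:subClassOf dnmso:AminoAcid ; rdfs:comment "Reduces to an amino acid but carries a modification reference." .
dnmso:Gap a rdfs:Class ; rdfs:comment "Unexplained mass stretch, monoisotopic Daltons." .
dnmso:Score a rdfs:Class .
dnmso:Modification a rdfs:Class ; rdfs:comment "Must reference a PSI-MOD term; records mono and average mass deltas." .
dnmso:Software a rdfs:Class .
dnmso:CVParam a rdfs:Class .
dnmso:UserParam a rdfs:Class .
dnmso:CVSource a rdfs:Class .

dnmso:localId a rdf:Property .
dnmso:creator a rdf:Property .
dnmso:created a rdf:Property .
dnmso:spectra a rdf:Property ; rdfs:comment "RDF list of Spectrum nodes (order-preserving)." .
dnmso:predictions a rdf:Property .
dnmso:modifications a rdf:Property .
dnmso:software a rdf:Property .
dnmso:cvSources a rdf:Property .
dnmso:precursorMz a rdf:Property ; rdfs:comment "Thomson, > 0; absent when unknown." .
dnmso:precursorCharge a rdf:Property ; rdfs:comment "Positive integer; absent when unknown (never guessed)." .
dnmso:nativeId a rdf:Property .
dnmso:retentionTime a rdf:Property ; rdfs:comment "Seconds." .
dnmso:fragmentation a rdf:Property ; rdfs:comment "CID | ETD | HCD | other." .
dnmso:peaksCsv a rdf:Property ; rdfs:comment "Inline peak list: one 'mz,intensity' line per peak, full precision." .
dnmso:externalRef a rdf:Property .
dnmso:filePath a rdf:Property .
dnmso:formatHint a rdf:Property .
dnmso:sequence a rdf:Property .
dnmso:elements a rdf:Property ; rdfs:comment "RDF list of sequence-element nodes." .
dnmso:residue a rdf:Property .
dnmso:modificationRef a rdf:Property .
dnmso:gapMass a rdf:Property .
dnmso:confidence a rdf:Property ; rdfs:comment "Per-element confidence in [0,1]." .
dnmso:supportingPeaks a rdf:Property ; rdfs:comment "Encoded 'spectrumId:peakIndex' pairs backing one sequence element." .
dnmso:scores a rdf:Property ; rdfs:comment "RDF list of Score nodes; at least one per prediction." .
dnmso:scoreName a rdf:Property .
dnmso:scoreValue a rdf:Property .
dnmso:cvAccession a rdf:Property .
dnmso:sourceSpectra a rdf:Property ; rdfs:comment "RDF list of Spectrum IRIs; at least one per prediction." .
dnmso:softwareRef a rdf:Property .
dnmso:rank a rdf:Property .
dnmso:psimodAccession a rdf:Property ; rdfs:comment "Pattern MOD:\\d{5}; required for every modification." .
dnmso:modName a rdf:Property .
dnmso:monoMassDelta a rdf:Property .
dnmso:avgMassDelta a rdf:Property .
dnmso:residueSpecificity a rdf:Property .
dnmso:terminus a rdf:Property .
dnmso:swName a rdf:Property .
dnmso:swVersion a rdf:Property .
dnmso:parameters a rdf:Property .
dnmso:cvRef a rdf:Property .
dnmso:paramName a rdf:Property .
dnmso:paramValue a rdf:Property .
dnmso:fullName a rdf:Property .
dnmso:version a rdf:Property .
dnmso:uri a rdf:Property .
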