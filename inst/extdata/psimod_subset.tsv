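# Curated subset of common protein modifications following PSI-MOD
# conventions (synthetic excerpt bundled for standalone use; not the full
# ontology). Columns: accession, name, monoisotopic delta (Da), average
# delta (Da), residue specificity, terminus.
accession	name	mono_delta	avg_delta	residues	terminus
MOD:00000	protein modification	0.000000	0.0000	any	none
MOD:00046	O-phospho-L-serine	79.966331	79.9799	S	none
MOD:00047	O-phospho-L-threonine	79.966331	79.9799	T	none
MOD:00048	O4'-phospho-L-tyrosine	79.966331	79.9799	Y	none
MOD:00696	phosphorylated residue	79.966331	79.9799	any	none
MOD:00719	L-methionine sulfoxide	15.994915	15.9994	M	none
MOD:00039	4-hydroxy-L-proline	15.994915	15.9994	P	none
MOD:01060	S-carboxamidomethyl-L-cysteine	57.021464	57.0513	C	none
MOD:00400	deamidated residue	0.984016	0.9848	NQ	none
MOD:00394	acetylated residue	42.010565	42.0367	any	none
MOD:00064	N6-acetyl-L-lysine	42.010565	42.0367	K	none
MOD:01458	alpha-amino acetylated residue	42.010565	42.0367	any	N-term
MOD:00599	monomethylated residue	14.015650	14.0266	any	none
MOD:00429	dimethylated residue	28.031300	28.0532	any	none
MOD:00430	trimethylated residue	42.046950	42.0797	K	none
MOD:00398	carbamylated residue	43.005814	43.0247	any	none
MOD:00040	2-pyrrolidone-5-carboxylic acid (pyro-Glu)	-17.026549	-17.0305	Q	N-term
MOD:01160	glycyl-glycine adduct (ubiquitin remnant)	114.042927	114.1026	K	none
MOD:00687	nitrated residue	44.985078	44.9976	Y	none
MOD:01090	biotinylated residue	226.077598	226.2954	K	none
MOD:00693	glutathionylated residue	305.068156	305.3076	C	none
MOD:00568	S-palmitoyl-L-cysteine	238.229666	238.4136	C	none
MOD:00115	cysteine disulfide (dehydro)	-1.007825	-1.0079	C	none
MOD:00767	myristoylated residue	210.198366	210.3556	any	N-term
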