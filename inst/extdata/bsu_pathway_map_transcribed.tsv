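# Pathway ids and display names appearing in the transcribed B. subtilis
# neighborhood fixtures.
pathway_id	pathway_name
bsu00130	Ubiquinone and other terpenoid-quinone biosynthesis
bsu00230	Purine metabolism
bsu00240	Pyrimidine metabolism
bsu00260	Glycine, serine and threonine metabolism
bsu00270	Cysteine and methionine metabolism
bsu00340	Histidine metabolism
bsu00350	Tyrosine metabolism
bsu00360	Phenylalanine metabolism
bsu00400	Phenylalanine, tyrosine and tryptophan biosynthesis
bsu00401	Novobiocin biosynthesis
bsu00770	Pantothenate and CoA biosynthesis
bsu00790	Folate biosynthesis
bsu00900	Terpenoid backbone biosynthesis
bsu00920	Sulfur metabolism
bsu00970	Aminoacyl-tRNA biosynthesis
bsu01110	Biosynthesis of secondary metabolites
bsu01130	Biosynthesis of antibiotics
bsu01200	Carbon metabolism
bsu01230	Biosynthesis of amino acids
bsu02020	Two-component system
bsu02030	Bacterial chemotaxis
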