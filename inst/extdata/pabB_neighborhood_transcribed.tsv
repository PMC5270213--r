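# Hand-transcribed +-10 gene neighborhood of the B. subtilis pabB gene
# (bsu:BSU00740), the putative PM homolog of the bacillibactin cluster's
# isochorismate synthase DhbC. ECs for folK and lysS, which the shortened
# printed annotation omits, are completed from their standard KEGG gene
# annotations. Pathway memberships are transcribed from the published
# per-pathway neighborhood counts.
replicon_id	ordinal	gene_id	strand	product	ec	pathways
bsu_chr	1	bsu:BSU00640	+	spoIIE; stage II sporulation protein E	3.1.3.16	bsu01200
bsu_chr	2	bsu:BSU00650	+	yabS; hypothetical protein
bsu_chr	3	bsu:BSU00660	+	yabT; serine/threonine protein kinase	2.7.11.1
bsu_chr	4	bsu:BSU00670	+	tilS; tRNA(ile)-lysidine synthase	6.3.4.19
bsu_chr	5	bsu:BSU00680	+	hprT; hypoxanthine-guanine phosphoribosyltransferase	2.4.2.8	bsu00230;bsu01110
bsu_chr	6	bsu:BSU00690	+	ftsH; ATP-dependent zinc metalloprotease FtsH	3.4.24.-
bsu_chr	7	bsu:BSU00700	+	coaX; type III pantothenate kinase	2.7.1.33	bsu00770
bsu_chr	8	bsu:BSU00710	+	hslO; 33 kDa chaperonin
bsu_chr	9	bsu:BSU00720	+	yacD; peptidyl-prolyl cis-trans isomerase
bsu_chr	10	bsu:BSU00730	+	cysK; cysteine synthase	2.5.1.47	bsu01110;bsu01130;bsu00270;bsu00920;bsu01230
bsu_chr	11	bsu:BSU00740	+	pabB; para-aminobenzoate synthase component I	2.6.1.85	bsu00790
bsu_chr	12	bsu:BSU00750	+	pabA; para-aminobenzoate/anthranilate synthase component II	2.6.1.85	bsu00790
bsu_chr	13	bsu:BSU00760	+	pabC; aminodeoxychorismate lyase	4.1.3.38	bsu00790
bsu_chr	14	bsu:BSU00770	+	sul; dihydropteroate synthase	2.5.1.15	bsu00790
bsu_chr	15	bsu:BSU00780	+	folB; dihydroneopterin aldolase	4.1.2.25	bsu00790
bsu_chr	16	bsu:BSU00790	+	folK; 2-amino-4-hydroxy-6-hydroxymethyldihydropteridine pyrophosphokinase	2.7.6.3	bsu00790
bsu_chr	17	bsu:BSU00800	+	yazB; XRE family transcriptional regulator
bsu_chr	18	bsu:BSU00810	+	dusB; tRNA-dihydrouridine synthase	1.-.-.-
bsu_chr	19	bsu:BSU00820	+	lysS; lysine--tRNA ligase	6.1.1.6	bsu00970
bsu_chr	20	bsu:BSU00830	+	ctsR; transcriptional regulator CtsR
bsu_chr	21	bsu:BSU00840	+	mcsA; protein arginine kinase activator
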