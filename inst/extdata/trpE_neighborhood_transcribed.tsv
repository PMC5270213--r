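# Hand-transcribed +-10 gene neighborhood of the B. subtilis trpE gene
# (bsu:BSU22680), the second genomic homolog of the bacillibactin cluster's
# isochorismate synthase DhbC. The published table prints only 20 distinct
# loci (its first row repeats at the end); BSU22580 is added as an
# unannotated padding gene so the window is a full 21 genes. Pathway
# memberships are transcribed from the published per-pathway counts.
replicon_id	ordinal	gene_id	strand	product	ec	pathways
bsu_chr	1	bsu:BSU22580	+	hypothetical protein
bsu_chr	2	bsu:BSU22590	+	ypiA; TPR repeat-containing protein YpiA
bsu_chr	3	bsu:BSU22600	+	aroE; 3-phosphoshikimate 1-carboxyvinyltransferase	2.5.1.19	bsu01110;bsu01130;bsu00400;bsu01230
bsu_chr	4	bsu:BSU22610	+	tyrA; prephenate dehydrogenase	1.3.1.12	bsu01110;bsu01130;bsu00400;bsu01230;bsu00350;bsu00360
bsu_chr	5	bsu:BSU22620	+	hisC; histidinol-phosphate aminotransferase	2.6.1.9	bsu01110;bsu01130;bsu00400;bsu01230;bsu00340
bsu_chr	6	bsu:BSU22630	+	trpA; tryptophan synthase alpha chain	4.2.1.20	bsu01110;bsu01130;bsu00400;bsu01230;bsu00260
bsu_chr	7	bsu:BSU22640	+	trpB; tryptophan synthase beta chain	4.2.1.20	bsu01110;bsu01130;bsu00400;bsu01230;bsu00260
bsu_chr	8	bsu:BSU22650	+	trpF; N-(5'-phosphoribosyl)anthranilate isomerase	5.3.1.24	bsu01110;bsu01130;bsu00400;bsu01230
bsu_chr	9	bsu:BSU22660	+	trpC; indole-3-glycerol phosphate synthase	4.1.1.48	bsu01110;bsu01130;bsu00400;bsu01230
bsu_chr	10	bsu:BSU22670	+	trpD; anthranilate phosphoribosyltransferase	2.4.2.18	bsu01110;bsu01130;bsu00400;bsu01230
bsu_chr	11	bsu:BSU22680	+	trpE; anthranilate synthase component 1	4.1.3.27	bsu01110;bsu01130;bsu00400;bsu01230
bsu_chr	12	bsu:BSU22690	+	aroH; chorismate mutase AroH	5.4.99.5	bsu01110;bsu01130;bsu00400;bsu01230
bsu_chr	13	bsu:BSU22700	+	aroB; 3-dehydroquinate synthase	4.2.3.4	bsu01110;bsu01130;bsu00400;bsu01230
bsu_chr	14	bsu:BSU22710	+	aroF; chorismate synthase	4.2.3.5	bsu01110;bsu01130;bsu00400;bsu01230;bsu00401
bsu_chr	15	bsu:BSU22720	+	cheR; chemotaxis protein methyltransferase	2.1.1.80	bsu02030;bsu00401
bsu_chr	16	bsu:BSU22730	+	ndk; nucleoside diphosphate kinase	2.7.4.6	bsu01110;bsu00240;bsu00230
bsu_chr	17	bsu:BSU22740	+	hepT; heptaprenyl diphosphate synthase component 2	2.5.1.30	bsu01110;bsu01130;bsu00900
bsu_chr	18	bsu:BSU22750	+	ubiE; demethylmenaquinone methyltransferase	2.1.1.-	bsu01110;bsu00130
bsu_chr	19	bsu:BSU22760	+	hepS; heptaprenyl diphosphate synthase component 1	2.5.1.30	bsu01110;bsu00900
bsu_chr	20	bsu:BSU22770	+	mtrB; transcription attenuation protein MtrB		bsu02020
bsu_chr	21	bsu:BSU22780	+	folE; GTP cyclohydrolase 1	3.5.4.16	bsu00790
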