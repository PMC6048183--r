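otu	samples	species	larvae	larval_type	cad_units	coi_units	assoc_cad	assoc_coi	recip_mono	n_criteria	note
H. acharai	4	H. acharai	yes	japonica	1/1	1/1	yes/yes	yes/yes	yes	5
H. anomala	6	H. anomala	yes	tibetana	1/1	4/3	yes/yes	no/yes	yes	4
H. auricularis	2	H. auricularis	no	unknown	1/1	2/1	-	-	not_applicable	-
H. biansata	2	H. biansata	no	unknown	no_data	1/1	-	-	not_applicable	-
H. diehli	1	H. diehli	no	unknown	1/1	1/1	-	-	not_applicable	-
H. digitata	34	H. digitata	yes	tibetana	2/1	2/2	yes/yes	no/no	yes	3
H. eos	2	H. eos	no	unknown	no_data	1/1	-	-	not_applicable	-
excisa-complex	31	H. excisa;H. placida;H. maitreya	yes	tibetana	1/1	5/2	no/no	no/no	no	0
H. gigantea	2	H. gigantea	no	gigantea	no_data	1/1	-	-	not_applicable	-
H. gregoryi	77	H. gregoryi	yes	tibetana	1/1	1/1	yes/yes	yes/yes	yes	5
H. gyamo	1	H. gyamo	no	unknown	1/1	1/1	-	-	not_applicable	-
H. horai	5	H. horai	no	unknown	1/1	1/1	-	-	yes	-
japonica-complex	8	H. japonica;H. sp. n. 1529	yes_no_dna	japonica	2/1	4/3	-	-	no	-	COI/CAD topology conflict; larvae lack DNA data
H. kuldschensis	2	H. kuldschensis	no	unknown	1/1	1/1	-	-	yes	-
H. lanceolata	4	H. lanceolata	no	unknown	1/1	1/1	-	-	yes	-
H. lepcha	5	H. lepcha	no	unknown	1/1	2/2	-	-	yes	-
H. lua	5	H. lua	no	unknown	no_data	2/1	-	-	not_applicable	-
martynovi-complex	30	H. martynovi;H. epikur	yes	tibetana	martynovi-clade	1/1	no/no	no/no	no	0	single merged CAD GMYC cluster (martynovi-clade)
H. navasi	4	H. navasi	no	unknown	1/1	4/4	-	-	not_applicable	-
H. phryganea	4	H. phryganea	yes	phryganea	1/1	2/2	yes/yes	yes/yes	yes	5
platon-complex	27	H. platon;H. sp (F);H. sp (L)	yes	tibetana	1/1	4/3	no/no	no/no	yes	1	no CAD data for the adult male
H. sp. 1196 (L)	17	NA	yes	tibetana	1/1	2/1	-	-	yes	-	larva-only OTU
H. sp. 1254 (L)	4	NA	yes	tibetana	1/1	no_data	-	-	not_applicable	-	larva-only OTU
H. sp. 1338 (L)	1	NA	yes	gigantea	1/1	1/1	-	-	not_applicable	-	larva-only OTU
H. sylvicola	33	H. sylvicola	yes	gigantea	1/1	6/3	yes/yes	yes/yes	yes	5	published COI association cell reads no/yes, inconsistent with the published count of 5; count column followed
H. tibetana	58	H. tibetana	yes	tibetana	1/1	2/2	yes/yes	yes/yes	yes	5
H. todma	4	H. todma	no	unknown	1/1	no_data	-	-	not_applicable	-
triloba-complex	67	H. triloba;H. hageni;H. maculipennis;H. malenanda;H. efiel;H. yatrawalla	yes	gigantea	2/2	5/3	no/no	no/no	no	0	COI/CAD topology conflict
H. yongma	1	H. yongma	no	unknown	1/1	1/1	-	-	not_applicable	-
H. 677	41	H. 677	yes	tibetana	1/1	1/1	yes/yes	yes/yes	yes	5
H. 683	8	H. 683	no	tibetana	martynovi-clade	1/1	-	-	yes	-	single merged CAD GMYC cluster (martynovi-clade)
H. 685	34	H. 685	yes	tibetana	martynovi-clade	1/1	no/no	yes/yes	yes	3	single merged CAD GMYC cluster (martynovi-clade)
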