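name	size	group	role	sequence
F1	20	selection	opposite_primer	TCCTTTACTTACTACACCTC
F2	20	selection	opposite_primer	&&&&&&&&&&&&&&CACCTCAGATATTTTTCTTC
F3	21	selection	opposite_primer	&&&&&&&&&&&&&&CACCTCAGATATTTTTCTTCA
F4	18	selection	allele_primer	&&TTTTGGTCTAGCCACAGA
F5	19	selection	allele_primer	&ATTTTGGTCTAGCCACAGA
F6	20	selection	allele_primer	GATTTTGGTCTAGCCACAGA
R1	17	selection	allele_primer	&&ACTCCATCGAGATTTCT
R2	18	selection	allele_primer	&CACTCCATCGAGATTTCT
R3	19	selection	allele_primer	CCACTCCATCGAGATTTCT
R4	19	selection	opposite_primer	&TTAATTAATGGAGAAATGG
R5	20	selection	opposite_primer	TTTAATTAATGGAGAAATGG
R6	20	selection	opposite_primer	&&ATTCTTACCATCCACAAAAT
R7	20	selection	opposite_primer	&AATTCTTACCATCCACAAAA
R8	20	selection	opposite_primer	CAATTCTTACCATCCACAAA
BR1	21	selection	blocker	&TCGAGATTTCACTGTGGCTAG-P
BR2	23	selection	blocker	ATCGAGATTTCACTGTGGCTAGA-P
BR3	24	selection	blocker	ATCGAGATTTCACTGTGGCTAGAC-P
BF1	21	selection	blocker	&&CTAGCCACAGTGAAATCTCGA-P
BF2	23	selection	blocker	&TCTAGCCACAGTGAAATCTCGAT-P
BF3	25	selection	blocker	GTCTAGCCACAGTGAAATCTCGATG-P
Primer_Fw_TA	21	ta_cloning	opposite_primer	CACCTCAGATATTTTTCTTCA
Primer_Rv_TA	20	ta_cloning	opposite_primer	CAATTCTTACCATCCACAAA
BRAF_Fw_BC1	60	nanopore	barcoded_primer	P-ATCGCCTACCGTGAC-AAGAAAGTTGTCGGTGTCTTTGTG-CACCTCAGATATTTTTCTTCA
BRAF_Fw_BC2	60	nanopore	barcoded_primer	P-ATCGCCTACCGTGAC-TCGATTCCGTTTGTAGTCGTCTGT-CACCTCAGATATTTTTCTTCA
BRAF_Fw_BC3	60	nanopore	barcoded_primer	P-ATCGCCTACCGTGAC-GAGTCTTGTGTCCCAGTTACCAGG-CACCTCAGATATTTTTCTTCA
BRAF_Fw_BC4	60	nanopore	barcoded_primer	P-ATCGCCTACCGTGAC-TTCGGATTCTATCGTGTTTCCCTA-CACCTCAGATATTTTTCTTCA
BRAF_Fw_BC5	60	nanopore	barcoded_primer	ATCGCCTACCGTGAC-CTTGTCCAGGGTTTGTGTAACCTT-CACCTCAGATATTTTTCTTCA
BRAF_Fw_BC6	60	nanopore	barcoded_primer	ATCGCCTACCGTGAC-TTCTCGCAAAGGCAGAAAGTAGTC-CACCTCAGATATTTTTCTTCA
BRAF_Rv	20	nanopore	opposite_primer	P-CAATTCTTACCATCCACAAA
Primer_Std_Fw	20	standard	opposite_primer	ATTTCAAGCCCCCAAAATCT
Primer_Std_Rv	20	standard	opposite_primer	CTGCAGATCGTACCTGCTGA
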