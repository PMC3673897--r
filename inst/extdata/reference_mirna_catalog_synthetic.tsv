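mature_seq	species	family	name
TTGACAGAAGATAGAGAGCAC	gma	MIR156	gma-miR156d
TGACAGAAGAGAGTGAGCAC	gma	MIR156	gma-miR156h
TTGACAGAAGATAGAGAGCAC	ath	MIR156	ath-miR156a
TTGACAGAAGATAGAGAGCAC	osa	MIR156	osa-miR156a
TTGACAGAAGATAGAGAGCAC	zma	MIR156	zma-miR156a
TTGACAGAAGATAGAGAGCAC	mtr	MIR156	mtr-miR156a
TTGACAGAAGATAGAGAGCAC	ptc	MIR156	ptc-miR156a
TTTGGATTGAAGGGAGCTCTA	gma	MIR159	gma-miR159e-3p
TTTGGATTGAAGGGAGCTCTA	ath	MIR159	ath-miR159a
TTTGGATTGAAGGGAGCTCTA	osa	MIR159	osa-miR159a
TTTGGATTGAAGGGAGCTCTA	zma	MIR159	zma-miR159a
TTTGGATTGAAGGGAGCTCTA	mtr	MIR159	mtr-miR159a
TTTGGATTGAAGGGAGCTCTA	ptc	MIR159	ptc-miR159a
GCGTATGAGGAGCCAAGCATA	gma	MIR160	gma-miR160f
GCGTATGAGGAGCCAAGCATA	ath	MIR160	ath-miR160a
GCGTATGAGGAGCCAAGCATA	osa	MIR160	osa-miR160a
GCGTATGAGGAGCCAAGCATA	zma	MIR160	zma-miR160a
GCGTATGAGGAGCCAAGCATA	mtr	MIR160	mtr-miR160a
GCGTATGAGGAGCCAAGCATA	ptc	MIR160	ptc-miR160a
TCGATAAACCTCTGCATCCAG	gma	MIR162	gma-miR162c
TCGATAAACCTCTGCATCCAG	ath	MIR162	ath-miR162a
TCGATAAACCTCTGCATCCAG	mtr	MIR162	mtr-miR162a
TCGATAAACCTCTGCATCCAG	ptc	MIR162	ptc-miR162a
TGGAGAAGCAGGGCACGTGCA	gma	MIR164	gma-miR164e
TGGAGAAGCAGGGCACGTGCA	ath	MIR164	ath-miR164a
TGGAGAAGCAGGGCACGTGCA	osa	MIR164	osa-miR164a
TGGAGAAGCAGGGCACGTGCA	zma	MIR164	zma-miR164a
TGGAGAAGCAGGGCACGTGCA	mtr	MIR164	mtr-miR164a
TGGAGAAGCAGGGCACGTGCA	ptc	MIR164	ptc-miR164a
TCGGACCAGGCTTCATTCCCC	gma	MIR166	gma-miR166g
TCGGACCAGGCTTCATTCCCC	ath	MIR166	ath-miR166a
TCGGACCAGGCTTCATTCCCC	osa	MIR166	osa-miR166a
TCGGACCAGGCTTCATTCCCC	zma	MIR166	zma-miR166a
TCGGACCAGGCTTCATTCCCC	mtr	MIR166	mtr-miR166a
TCGGACCAGGCTTCATTCCCC	ptc	MIR166	ptc-miR166a
TGAAGCTGCCAGCATGATCTT	gma	MIR167	gma-miR167e
TGAAGCTGCCAGCATGATCTT	ath	MIR167	ath-miR167a
TGAAGCTGCCAGCATGATCTT	osa	MIR167	osa-miR167a
TGAAGCTGCCAGCATGATCTT	zma	MIR167	zma-miR167a
TGAAGCTGCCAGCATGATCTT	mtr	MIR167	mtr-miR167a
TGAAGCTGCCAGCATGATCTT	ptc	MIR167	ptc-miR167a
TCGCTTGGTGCAGGTCGGGAA	gma	MIR168	gma-miR168
TCGCTTGGTGCAGGTCGGGAA	ath	MIR168	ath-miR168a
TCGCTTGGTGCAGGTCGGGAA	osa	MIR168	osa-miR168a
TCGCTTGGTGCAGGTCGGGAA	zma	MIR168	zma-miR168a
TCGCTTGGTGCAGGTCGGGAA	mtr	MIR168	mtr-miR168a
TCGCTTGGTGCAGGTCGGGAA	ptc	MIR168	ptc-miR168a
AAGCCAAGGATGACTTGCCGA	gma	MIR169	gma-miR169c
AAGCCAAGGATGACTTGCCGA	ath	MIR169	ath-miR169a
AAGCCAAGGATGACTTGCCGA	osa	MIR169	osa-miR169a
AAGCCAAGGATGACTTGCCGA	zma	MIR169	zma-miR169a
AAGCCAAGGATGACTTGCCGA	mtr	MIR169	mtr-miR169a
AAGCCAAGGATGACTTGCCGA	ptc	MIR169	ptc-miR169a
AGAATCTTGATGATGCTGCAT	gma	MIR172	gma-miR172b-3p
AGAATCTTGATGATGCTGCAT	ath	MIR172	ath-miR172a
AGAATCTTGATGATGCTGCAT	osa	MIR172	osa-miR172a
AGAATCTTGATGATGCTGCAT	zma	MIR172	zma-miR172a
AGAATCTTGATGATGCTGCAT	mtr	MIR172	mtr-miR172a
AGAATCTTGATGATGCTGCAT	ptc	MIR172	ptc-miR172a
AAGCTCAGGAGGGATAGCACC	gma	MIR390	gma-miR390b
AAGCTCAGGAGGGATAGCACC	ath	MIR390	ath-miR390a
AAGCTCAGGAGGGATAGCACC	osa	MIR390	osa-miR390a
AAGCTCAGGAGGGATAGCACC	zma	MIR390	zma-miR390a
AAGCTCAGGAGGGATAGCACC	mtr	MIR390	mtr-miR390a
AAGCTCAGGAGGGATAGCACC	ptc	MIR390	ptc-miR390a
TTCCACAGCTTTCTTGAACTG	gma	MIR396	gma-miR396a-5p
TTCCACAGCTTTCTTGAACTG	ath	MIR396	ath-miR396a
TTCCACAGCTTTCTTGAACTG	osa	MIR396	osa-miR396a
TTCCACAGCTTTCTTGAACTG	zma	MIR396	zma-miR396a
TTCCACAGCTTTCTTGAACTG	mtr	MIR396	mtr-miR396a
TTCCACAGCTTTCTTGAACTG	ptc	MIR396	ptc-miR396a
TCATTGAGTGCAGCGTTGATG	gma	MIR397	gma-miR397a
TCATTGAGTGCAGCGTTGATG	ath	MIR397	ath-miR397a
TCATTGAGTGCAGCGTTGATG	osa	MIR397	osa-miR397a
TCATTGAGTGCAGCGTTGATG	zma	MIR397	zma-miR397a
TCATTGAGTGCAGCGTTGATG	ptc	MIR397	ptc-miR397a
TGCCAAAGGAGATTTGCCCAG	gma	MIR399	gma-miR399a
TGCCAAAGGAGATTTGCCCAG	ath	MIR399	ath-miR399a
TGCCAAAGGAGATTTGCCCAG	osa	MIR399	osa-miR399a
TGCCAAAGGAGATTTGCCCAG	mtr	MIR399	mtr-miR399a
TGCCAAAGGAGATTTGCCCAG	ptc	MIR399	ptc-miR399a
TTGCCGATTCCACCCATTCCTA	gma	MIR2118	gma-miR2118a
TTGCCGATTCCACCCATTCCTA	osa	MIR2118	osa-miR2118a
TTGCCGATTCCACCCATTCCTA	zma	MIR2118	zma-miR2118a
TTGCCGATTCCACCCATTCCTA	mtr	MIR2118	mtr-miR2118a
TTGCCGATTCCACCCATTCCTA	ptc	MIR2118	ptc-miR2118a
ATGCACTGCCTCTTCCCTGGC	gma	MIR408	gma-miR408c
ATGCACTGCCTCTTCCCTGGC	ath	MIR408	ath-miR408a
ATGCACTGCCTCTTCCCTGGC	osa	MIR408	osa-miR408a
ATGCACTGCCTCTTCCCTGGC	zma	MIR408	zma-miR408a
ATGCACTGCCTCTTCCCTGGC	mtr	MIR408	mtr-miR408a
ATGCACTGCCTCTTCCCTGGC	ptc	MIR408	ptc-miR408a
TCTTCCCTACACCTCCCATACC	gma	MIR482	gma-miR482b-3p
TCTTCCCTACACCTCCCATACC	ptc	MIR482	ptc-miR482a
TCTCATTCCATACATCGTCTGA	gma	MIR1507	gma-miR1507a
TCTCATTCCATACATCGTCTGA	mtr	MIR1507	mtr-miR1507a
TAGAAAGGGAAATAGCAGTTG	gma	MIR1508	gma-miR1508d
TTAATCAAGGAAATCACGGTCG	gma	MIR1509	gma-miR1509a
TTAATCAAGGAAATCACGGTCG	mtr	MIR1509	mtr-miR1509a
AGGGATAGGTAAAACAACTACT	gma	MIR1510	gma-miR1510b-5p
AGGGATAGGTAAAACAACTACT	mtr	MIR1510	mtr-miR1510a
TGCGAGTGTCTTCGCCTCTGA	gma	MIR2109	gma-miR2109a
TGAGACCAAATGAGCAGCTGAC	gma	MIR3522	gma-miR3522a
AACCAGGCTCTGATACCATGG	gma	MIR1511	gma-miR1511
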