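mirna	sequence	platform	probe
mmu-miR-15a	UAGCAGCACAUAAUGGUUUGUG	agilent	CACAAACCATTATGTGCTGCT(A)
mmu-miR-15a	UAGCAGCACAUAAUGGUUUGUG	affymetrix	CACAAACCATTATGTGCTGCTA
mmu-miR-21	UAGCUUAUCAGACUGAUGUUGA	agilent	TCAACATCAGTCTGATAAG(C)
mmu-miR-21	UAGCUUAUCAGACUGAUGUUGA	affymetrix	TCAACATCAGTCTGATAAGCTA
mmu-miR-34a	UGGCAGUGUCUUAGCUGGUUGU	agilent	ACAACCAGCTAAGACACTG(C)
mmu-miR-34a	UGGCAGUGUCUUAGCUGGUUGU	affymetrix	ACAACCAGCTAAGACACTGCCA
mmu-miR-96	UUUGGCACUAGCACAUUUUUGCU	agilent	AGCAAAAATGTGCTAGTGCCA(A)
mmu-miR-96	UUUGGCACUAGCACAUUUUUGCU	affymetrix	AGCAAAAATGTGCTAGTGCCAAA
mmu-miR-127	UCGGAUCCGUCUGAGCUUGGCU	agilent	AGCCAAGCTCAGACGGA(T)
mmu-miR-127	UCGGAUCCGUCUGAGCUUGGCU	affymetrix	AGCCAAGCTCAGACGGATCCGA
mmu-miR-146a	UGAGAACUGAAUUCCAUGGGUU	agilent	AACCCATGGAATTCAGTT(C)
mmu-miR-146a	UGAGAACUGAAUUCCAUGGGUU	affymetrix	AACCCATGGAATTCAGTTCTCA
mmu-miR-146b	UGAGAACUGAAUUCCAUAGGCU	agilent	AGCCTATGGAATTCAGTT(C)
mmu-miR-146b	UGAGAACUGAAUUCCAUAGGCU	affymetrix	AGCCTATGGAATTCAGTTCTCA
mmu-miR-182	UUUGGCAAUGGUAGAACUCACACCG	agilent	CGGTGTGAGTTCTAC(C)
mmu-miR-182	UUUGGCAAUGGUAGAACUCACACCG	affymetrix	CGGTGTGAGTTCTACCATTGCCAAA
mmu-miR-183	UAUGGCACUGGUAGAAUUCACU	agilent	AGTGAATTCTACCAGTGC(C)
mmu-miR-183	UAUGGCACUGGUAGAAUUCACU	affymetrix	AGTGAATTCTACCAGTGCCATA
mmu-miR-184	UGGACGGAGAACUGAUAAGGGU	agilent	ACCCTTATCAGTTCTCCGTCC(A)
mmu-miR-184	UGGACGGAGAACUGAUAAGGGU	affymetrix	ACCCTTATCAGTTCTCCGTCCA
mmu-miR-322	CAGCAGCAAUUCAUGUUUUGGA	agilent	TCCAAAACATGAATTGCTGCTG
mmu-miR-322	CAGCAGCAAUUCAUGUUUUGGA	affymetrix	TCCAAAACATGAATTGCTGCTG
mmu-miR-433	AUCAUGAUGGGCUCCUCGGUGU	agilent	ACACCGAGGAGCC(C)
mmu-miR-433	AUCAUGAUGGGCUCCUCGGUGU	affymetrix	ACACCGAGGAGCCCATCATGAT
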