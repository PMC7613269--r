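species	genome	assay_set	primer	sequence	coordinates	role_dpnii	role_nlaiii
Homo sapiens	hg38	Hs 1	forward	GTCAGAAATAACAGGAAACCCAAA	chr22:46257116-46257137	cut_site	cut_site
Homo sapiens	hg38	Hs 1	reverse	TTACTTGTCGAACCCAGAAGAC	chr22:46257190-46257212	cut_site	cut_site
Homo sapiens	hg38	Hs 2	forward	GAGAATGGCCACATACAAGTAGA	chr22:46257407-46257429	fragment	fragment
Homo sapiens	hg38	Hs 2	reverse	GGAGTTGTCAACACAAGCATATC	chr22:46257480-46257502	fragment	fragment
Mus musculus	mm9	Mm 1	forward	GGAGAAAGAAGGCTGGTGTTAT	chr15:85650603-85650624	cut_site	fragment
Mus musculus	mm9	Mm 1	reverse	TATCTGAGTTGGACAGCATTGG	chr15:85650686-85650707	cut_site	fragment
Mus musculus	mm9	Mm 2	forward	TTATCTTGCATTTGCCAACTCG	chr15:85650801-85650822	fragment	cut_site
Mus musculus	mm9	Mm 2	reverse	TGGGTTTCCCTGATTCTGAAA	chr15:85650880-85650900	fragment	cut_site
Drosophila melanogaster	dm6	Dm 1	forward	CAGGCCAACACACATTGTATC	chr3R:23023063-23023083	cut_site	NA
Drosophila melanogaster	dm6	Dm 1	reverse	CGGCAGGCAAATCGAATAAA	chr3R:23023146-23023165	cut_site	NA
Drosophila melanogaster	dm6	Dm 2	forward	TGTTAGTCCCTGCCTCTGTA	chr3R:23023278-23023297	fragment	NA
Drosophila melanogaster	dm6	Dm 2	reverse	AAGTAACAGCAGCTGGAATAGG	chr3R:23023358-23023379	fragment	NA
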