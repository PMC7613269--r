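chr16	226254	227156	HBA1
chr16	222450	223352	HBA2
chr8	128748253	128748439	MYC
chr8	23385780	23386686	SLC25A37
chr11	5247977	5248607	HBB
chr11	5255391	5256556	HBD
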