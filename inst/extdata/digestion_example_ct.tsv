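sample	assay	ct
control1	cut_site	21.043
control1	fragment	21.211
control2	cut_site	23.422
control2	fragment	20.884
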