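organ_name,tolerance_gy,endpoint_kind,note
optical_pathway,8,D2cc,lowest cranial tolerance; drives the 30% tumor-space safety bound
brainstem,12,Dmax,placeholder - replace with institutional limit
cochlea,9,Dmean,placeholder - replace with institutional limit
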