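epitope,length_aa
RPAPGS(GalNAc)TAPPAHG,13
PAHGVT(GalNAc)SAPD,10
PAHGVTS(GalNAc)APD,10
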