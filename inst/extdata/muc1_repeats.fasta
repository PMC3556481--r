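>muc1_repeat_rp one circular phase of the 20-aa MUC1 tandem repeat
RPAPGSTAPPAHGVTSAPDT
>muc1_repeat_hg alternative phase of the same repeat
HGVTSAPDTRPAPGSTAPPA
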