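# glycoforge glycan alphabet (state 0 = UNOCCUPIED, implicit)
GalNAc	C8H13NO5
NeuAc-GalNAc	C8H13NO5+C11H17NO8
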