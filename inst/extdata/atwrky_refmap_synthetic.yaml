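AtWRKY11: IId
AtWRKY14: IIe
AtWRKY18: IIa
AtWRKY20: I
AtWRKY21: IId
AtWRKY27: IIe
AtWRKY28: IIc
AtWRKY31: IIb
AtWRKY41: III
AtWRKY43: IIc
AtWRKY45: I
AtWRKY49: IIc
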