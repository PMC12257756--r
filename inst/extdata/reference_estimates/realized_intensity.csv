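trait,intensity
ED03,2.237
ED01,2.071
TD03,1.904
TD01,1.788
AD01,2.036
NBP,1.963
SD06,2.137
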