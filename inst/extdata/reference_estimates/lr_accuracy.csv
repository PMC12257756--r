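trait,accuracy
ED03,0.350
ED01,0.318
TD03,0.281
TD01,0.273
AD01,0.305
NBP,0.317
SD06,0.357
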