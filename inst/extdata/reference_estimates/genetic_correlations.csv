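trait,ED03,ED01,TD03,TD01,AD01,NBP,SD06
ED03,1,0.971,0.444,0.409,0.835,0.846,0.893
ED01,0.971,1,0.448,0.418,0.847,0.876,0.880
TD03,0.444,0.448,1,0.849,0.808,0.779,0.800
TD01,0.409,0.418,0.849,1,0.824,0.804,0.730
AD01,0.835,0.847,0.808,0.824,1,0.994,0.960
NBP,0.846,0.876,0.779,0.804,0.994,1,0.952
SD06,0.893,0.880,0.800,0.730,0.960,0.952,1
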