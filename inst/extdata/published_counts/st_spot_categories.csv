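category,n_spots
mCAFhigh_endohigh,964
mCAFhigh_endolow,416
mCAFlow_endohigh,291
mCAFlow_endolow,1414
other,11891
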