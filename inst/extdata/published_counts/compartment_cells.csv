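compartment,n_cells
tumor,266172
endothelia,1349
immune,50432
CAF,90986
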