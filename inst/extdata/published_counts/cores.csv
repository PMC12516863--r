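status,role,n_cores
retained,primary,188
retained,metastasis,11
excluded,NA,58
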