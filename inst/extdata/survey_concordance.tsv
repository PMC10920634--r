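analyte	chem_positive	both_positive
theobromine	96	62
theophylline	26	21
caffeine	81	62
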