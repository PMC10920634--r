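region	n_analyzed_adna	n_cacao_positive	n_herrania_positive
South America	118	73	27
Central America	39	26	4
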