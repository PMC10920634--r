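key	value
items_both_methods	120
adna_positive_among_both	85
south_america_items_methylxanthine	311
south_america_theobromine_positive	116
mapped_to_cacao_genome	618048
cacao_first_hit	19836
herrania_first_hit	1059
adna_items_analyzed	157
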