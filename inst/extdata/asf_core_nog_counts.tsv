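quantity	count
unique_nogs_observed	135013
core_nogs	3611
core_covered_by_consortium	2820
core_unique_single_species	1283
core_unique_top_species	1036
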