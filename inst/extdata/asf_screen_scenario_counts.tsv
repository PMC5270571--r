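growth	spent_call	double_call	count
growth	High	High	146
growth	Medium	Medium	416
growth	Low	Low	52
growth	High	Low	2
growth	High	Medium	30
growth	Medium	Low	41
growth	Low	High	9
growth	Low	Medium	51
growth	Medium	High	273
no_growth	High	High	460
no_growth	Medium	Medium	1426
no_growth	Low	Low	195
no_growth	High	Low	3
no_growth	High	Medium	43
no_growth	Medium	Low	39
no_growth	Low	High	10
no_growth	Low	Medium	85
no_growth	Medium	High	289
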