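population	n_screened	n_positive
AK	36	6
PNW	88	11
RM	62	2
UT	29	15
MW	108	4
EA	30	1
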