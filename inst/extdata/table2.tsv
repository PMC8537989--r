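category	n	pct
none	5	17.2
deletion	8	27.6
insertion	4	13.8
deletion_and_insertion	12	41.4
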