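# Synthetic human-like TERC layout (approximate; edit for real species).
# Intervals are 1-based inclusive; more specific domains listed first
# so they win overlap ties.
terc_length = 451
template = 46-56
J2a/3 = 171-205
pseudoknot = 1-210
CR4/CR5 = 241-330
scaRNA = 331-451
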