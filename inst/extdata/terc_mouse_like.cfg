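# Synthetic mouse-like TERC layout (5'-truncated; approximate).
# Intervals are 1-based inclusive; more specific domains listed first.
terc_length = 397
template = 3-13
J2a/3 = 120-160
pseudoknot = 1-150
CR4/CR5 = 220-320
scaRNA = 331-397
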