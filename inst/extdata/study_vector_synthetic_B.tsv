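mismatch_type	value
A-C	1.84
A-G	1.21
A-T	1.56
T-A	1.08
T-C	0.95
T-G	1.33
C-A	0.42
C-G	0.77
C-T	0.66
G-A	0.38
G-C	0.58
G-T	1.02
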