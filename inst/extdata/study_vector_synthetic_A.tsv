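mismatch_type	value
A-C	0.64
A-G	0.78
A-T	0.71
T-A	0.86
T-C	0.79
T-G	0.91
C-A	1.31
C-G	1.12
C-T	1.02
G-A	1.18
G-C	1.16
G-T	0.99
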