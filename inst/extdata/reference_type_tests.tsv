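mismatch_type	p_center_vs_five	p_center_vs_three	p_five_vs_three	frequency
A-C	0.00187	0.000128	0.525	673
A-G	6.29e-05	6.78e-10	0.0423	2567
A-T	2.78e-08	8.31e-10	0.747	553
T-A	0.0821	0.00499	0.328	506
T-C	0.00733	0.047	0.461	2920
T-G	0.553	0.185	0.422	435
C-A	0.187	2.54e-09	1.89e-06	778
C-G	0.000115	3.1e-06	0.377	627
C-T	1.47e-14	2.13e-46	1.66e-12	2874
G-A	2.17e-06	8.23e-19	6.08e-05	2624
G-C	0.00103	2.76e-05	0.339	687
G-T	0.0126	5.62e-05	0.103	556
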