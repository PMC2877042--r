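position	n_pairs
1	689
2	614
3	678
4	644
5	590
6	672
7	667
8	639
9	682
10	587
11	596
12	533
13	521
14	540
15	547
16	559
17	642
18	633
19	630
20	622
21	686
22	667
23	652
24	763
25	747
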