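# Observed per-clone deviation histograms from venom phospholipase A2
# clone screens of two pitviper specimens (sample codes B664 and
# ROM 39382), after UPGMA grouping into two putative-allele groups per
# specimen. n = clones in group, length = average scored sequence
# length (bp), k = deviations from the group consensus, observed =
# number of clones with exactly k deviations, expected_printed = the
# published expected counts (rounded) under the binomial error model
# at the calibration rate 95/58592 per site.
group	n	length	k	observed	expected_printed
B664_A	42	1754	0	4	2
B664_A	42	1754	1	5	7
B664_A	42	1754	2	11	10
B664_A	42	1754	3	5	8
B664_A	42	1754	4	7	7
B664_A	42	1754	5	8	4
B664_A	42	1754	6	2	2
B664_A	42	1754	7	0	1
B664_B	25	1724	0	1	2
B664_B	25	1724	1	6	4
B664_B	25	1724	2	9	6
B664_B	25	1724	3	6	6
B664_B	25	1724	4	2	4
B664_B	25	1724	5	1	2
B664_B	25	1724	6	0	1
B664_B	25	1724	7	0	0
ROM39382_A	44	1847	0	3	2
ROM39382_A	44	1847	1	7	7
ROM39382_A	44	1847	2	7	10
ROM39382_A	44	1847	3	11	10
ROM39382_A	44	1847	4	11	7
ROM39382_A	44	1847	5	2	4
ROM39382_A	44	1847	6	3	2
ROM39382_A	44	1847	7	0	1
ROM39382_B	23	1694	0	1	1
ROM39382_B	23	1694	1	2	4
ROM39382_B	23	1694	2	3	6
ROM39382_B	23	1694	3	8	5
ROM39382_B	23	1694	4	5	3
ROM39382_B	23	1694	5	3	2
ROM39382_B	23	1694	6	1	1
ROM39382_B	23	1694	7	0	0
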