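L=12
cpd1	active	1 2 3 4 5 9 10
cpd2	active	1 2 3 4 6
cpd3	active	1 2 3 4 5 6 11 12
cpd4	active	1 2 3 4 5 6 7
cpd5	active	1 2 3 5 6
cpd6	active	1 2 4 5 6 12
cpd7	active	1 2 3 4 5 6 11
cpd8	active	2 3 6
cpd9	active	1 2 3 4 5 6 8 9 10
cpd10	active	1 2 3 4 6 12
cpd11	active	1 2 4 5 6 12
cpd12	active	1 2 3 4
cpd13	active	1 3 4 5 6
cpd14	active	2 3 4 6 11
cpd15	active	1 2 4 5 6 10
cpd16	active	1 2 3 4 6 10
cpd17	active	1 2 5 6 10 12
cpd18	active	1 2 4 5 6
cpd19	inactive	3 6 8 9 10 11 12
cpd20	inactive	7 8 9 10 11 12
cpd21	inactive	3 7 8 9 10 11 12
cpd22	inactive	3 8 10 11
cpd23	inactive	7 9 10 11 12
cpd24	inactive	4 8 9 10 11 12
cpd25	inactive	2 3 4 7 8 9 10 11 12
cpd26	inactive	7 8 9 10 11
cpd27	inactive	2 6 7 8 10
cpd28	inactive	1 7 9 11 12
cpd29	inactive	4 7 9 10 11 12
cpd30	inactive	2 7 8 11 12
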