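i	j	r0
1	5	6.20284207374339
1	18	4.61312860042594
1	19	5.82885799383995
2	6	6.20284207374339
2	18	7.70562285446096
3	7	6.20284207374339
4	8	6.20284207374339
4	15	6.38991044413518
4	18	6.19825836118731
5	15	4.75758784495483
5	18	7.04878251990694
8	14	6.45871743639845
8	15	6.54948022870278
12	16	6.20284207374339
13	17	6.20284207374339
14	18	6.20284207374339
15	19	6.20284207374339
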