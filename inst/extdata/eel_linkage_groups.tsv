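# Japanese eel ddRAD linkage map, per-linkage-group summary (19 groups)
linkage_group	total_markers	female_markers	female_length_cM	male_markers	male_length_cM	anchored_scaffolds	anchored_bp
1	154	83	139.2	73	96.9	86	10779947
2	185	109	109.7	84	85.1	80	11549278
3	127	60	74.1	70	19.6	46	6166433
4	193	100	93.5	102	66.7	84	11926296
5	144	88	117.9	58	96.2	73	8932484
6	133	72	84.1	63	53.0	52	6456950
7	227	106	138.4	127	99.5	100	14079542
8	163	89	112.8	79	92.9	77	7915729
9	204	101	101.7	108	76.3	95	11854887
10	123	63	56.1	66	40.2	59	7250929
11	152	86	79.8	75	48.0	64	5754071
12	154	95	80.9	65	53.0	60	8740852
13	131	67	74.8	67	63.4	57	5716409
14	133	71	68.7	63	52.9	61	8348650
15	88	71	100.4	22	76.3	46	4849938
16	151	87	89.0	69	79.4	67	6927157
17	54	32	52.9	22	55.1	21	915430
18	123	68	57.9	60	47.2	54	3975438
19	148	79	116.9	73	92.8	69	9131346
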