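preset	decay_tau1	decay_tau2	decay_w1	decay_w2	decay_wss	rec_tau1	rec_tau2	rec_w1	rec_w2	act_v_half	act_slope	ssi_v_half	ssi_slope
CG	11	120	72	25	3	8	68	80	20	-25	19	-76	8.4
K3a+DPP6a	6.0	461	71	22	7	15.3	NA	100	NA	-26.5	17.9	-63.3	4.3
K3a+DPP6S	39.4	177	63	30	7	24.4	NA	100	NA	-25.7	19.8	-64.9	4.7
K3a+DPP6K	35.0	189	74	21	4	43	265	29	72	-20.1	18.9	-72.4	3.7
K3a+noDPP6	42.2	192	24	69	6	76.7	NA	100	NA	-17.4	20.4	-61.2	3.6
K3a+DPP6K_dN16	70.1	156	40	51	9	32.5	NA	100	NA	-15.8	18.2	-60.2	3.4
K3a+aK_1to1	7.4	131	69	15	16	11.0	199	91	9	-25.6	18.3	-66.0	4.5
K3a+aK_1to2	6.9	107	70	16	13	10.6	156	88	12	-25.6	16.4	-68.8	4.5
K3a+aK_1to3	8.5	122	65	25	10	14.5	207	79	21	-22.9	17.2	-69.6	4.5
K4bL+aK_1to2	5.1	67	71	16	12	14.3	145	63	37	-30.9	12.1	-70.6	4.5
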