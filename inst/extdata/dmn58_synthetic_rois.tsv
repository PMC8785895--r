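label	x	y	z
DMN_01	-3	52	7
DMN_02	3	44	21
DMN_03	6	-62	23
DMN_04	-4	-59	44
DMN_05	-50	-57	24
DMN_06	35	-61	33
DMN_07	-62	-21	-23
DMN_08	61	-27	-16
DMN_09	-13	-19	-18
DMN_10	31	-35	-8
DMN_11	-21	37	45
DMN_12	18	32	47
DMN_13	-16	56	-10
DMN_14	5	52	-1
DMN_15	-2	57	4
DMN_16	4	45	27
DMN_17	0	-54	35
DMN_18	6	-53	40
DMN_19	-53	-68	31
DMN_20	44	-72	23
DMN_21	-55	-29	-13
DMN_22	61	-28	-19
DMN_23	-30	-41	-14
DMN_24	35	-23	-20
DMN_25	-30	39	42
DMN_26	18	29	53
DMN_27	-16	49	-5
DMN_28	1	45	0
DMN_29	0	59	0
DMN_30	-7	38	16
DMN_31	3	-57	27
DMN_32	-13	-61	40
DMN_33	-48	-56	28
DMN_34	45	-57	31
DMN_35	-69	-21	-4
DMN_36	55	-22	-17
DMN_37	-20	-23	-13
DMN_38	33	-30	-18
DMN_39	-26	38	36
DMN_40	22	34	49
DMN_41	-8	54	-9
DMN_42	8	42	-15
DMN_43	-5	53	-2
DMN_44	2	44	24
DMN_45	2	-51	32
DMN_46	-7	-61	40
DMN_47	-46	-65	25
DMN_48	33	-60	38
DMN_49	-65	-24	-19
DMN_50	55	-31	-12
DMN_51	-27	-28	-10
DMN_52	25	-33	-17
DMN_53	-24	27	40
DMN_54	24	19	51
DMN_55	6	63	-3
DMN_56	9	41	1
DMN_57	13	47	7
DMN_58	-3	50	17
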