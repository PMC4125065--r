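chrom	pos	ref_counts	var_counts	vaf
1	14346	97	53	0.35333
1	14359	98	52	0.34667
1	26474	75	75	0.5
1	50463	87	63	0.42
1	56301	94	56	0.37333
1	64579	79	71	0.47333
1	78059	82	68	0.45333
1	80898	20	2	0.09091
1	83208	71	79	0.52667
1	84196	97	53	0.35333
1	86689	86	64	0.42667
1	101914	100	50	0.33333
1	113404	76	74	0.49333
1	116824	136	14	0.09333
1	152887	73	77	0.51333
1	173426	78	72	0.48
1	181425	84	66	0.44
1	182232	79	71	0.47333
1	219145	81	69	0.46
1	220962	83	67	0.44667
1	255052	88	62	0.41333
1	274822	83	67	0.44667
1	283706	82	68	0.45333
1	284918	78	72	0.48
1	301648	81	69	0.46
1	303704	75	75	0.5
1	307289	84	66	0.44
1	315192	82	68	0.45333
1	337382	84	66	0.44
1	343811	110	40	0.26667
1	344060	129	21	0.14
1	350287	75	75	0.5
1	375535	92	58	0.38667
1	376489	90	60	0.4
1	411838	105	45	0.3
1	418516	84	66	0.44
1	427825	84	66	0.44
1	437567	78	72	0.48
1	440894	97	53	0.35333
1	450574	81	69	0.46
1	472674	76	74	0.49333
1	476409	132	18	0.12
1	478064	83	67	0.44667
1	500396	93	57	0.38
1	508189	85	65	0.43333
1	536857	80	70	0.46667
1	553911	136	14	0.09333
1	556939	70	80	0.53333
1	558145	78	72	0.48
1	559938	89	61	0.40667
1	584969	132	18	0.12
1	603599	101	49	0.32667
1	609101	136	14	0.09333
1	619892	134	16	0.10667
1	622233	86	64	0.42667
1	626164	107	43	0.28667
1	628186	102	48	0.32
1	639519	80	70	0.46667
1	645184	135	15	0.1
1	645968	82	68	0.45333
1	647765	81	69	0.46
1	659051	132	18	0.12
1	680495	113	37	0.24667
1	698402	20	9	0.31034
1	702494	86	64	0.42667
1	719579	74	76	0.50667
1	739114	102	48	0.32
1	741556	82	68	0.45333
1	746038	94	56	0.37333
1	755450	98	52	0.34667
1	766170	133	17	0.11333
1	783130	72	78	0.52
1	786801	104	46	0.30667
1	813619	20	2	0.09091
1	826004	83	67	0.44667
1	829687	20	6	0.23077
1	837714	112	38	0.25333
1	852732	86	64	0.42667
1	854043	86	64	0.42667
1	861293	138	12	0.08
1	878792	77	73	0.48667
1	911285	132	18	0.12
1	912265	93	57	0.38
1	913140	130	20	0.13333
1	916500	83	67	0.44667
1	939744	128	22	0.14667
1	941177	113	37	0.24667
1	959673	135	15	0.1
1	965256	76	74	0.49333
1	985107	78	72	0.48
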