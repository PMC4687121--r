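symbol	p	fc_q150	fc_yac	abs_fc_diff
Actn2	1.07E-03	-0.19	-0.79	0.60
Htr2a	2.12E-04	-0.15	0.37	0.52
Ifit1	5.88E-03	-0.03	0.41	0.44
Galnt13	5.89E-05	-0.03	-0.45	0.42
Htt	3.19E-10	-0.32	0.09	0.41
Lgals3bp	9.45E-03	-0.04	0.36	0.40
Iqub	3.74E-03	-0.33	0.04	0.37
Ifi27l1	3.33E-04	-0.06	0.31	0.37
Usp18	1.32E-03	-0.08	0.28	0.36
Dpp10	2.03E-03	-0.07	0.26	0.34
Pkp2	9.91E-05	0.04	-0.29	0.33
Olfr174	4.74E-03	0.15	-0.18	0.33
Trim30	5.90E-04	-0.11	0.21	0.32
Trpc6	6.67E-03	-0.27	0.02	0.29
Zfp185	8.12E-03	-0.09	0.19	0.28
Grk4	4.41E-03	-0.06	0.21	0.27
Acot9	4.17E-04	-0.10	0.17	0.26
Lgals2	6.58E-03	0.29	0.05	0.25
Rreb1	2.71E-03	-0.11	0.14	0.24
Dpysl5	1.39E-03	0.20	-0.04	0.24
Ceacam2	9.51E-03	-0.16	0.08	0.24
Wdr78	5.63E-03	-0.27	-0.03	0.24
Dnajc5g	5.58E-03	-0.11	0.13	0.23
Ccdc108	8.86E-03	-0.06	0.17	0.23
Plac8l1	3.01E-03	0.13	-0.10	0.23
Rell2	9.35E-03	0.19	-0.04	0.22
Tnfsf8	1.67E-03	0.10	-0.12	0.22
Pabpc1l2b	7.47E-03	0.20	-0.01	0.22
Slc13a5	7.14E-03	-0.15	0.07	0.21
Irf9	1.68E-03	-0.05	0.16	0.21
Ranbp2	5.60E-03	-0.17	0.04	0.21
Fut4	7.54E-03	-0.16	0.05	0.21
Tpbg	4.70E-03	0.09	-0.11	0.21
Rnf213	4.48E-03	-0.01	0.20	0.20
Speer2	4.22E-03	0.14	-0.06	0.20
V1rb3	5.18E-03	0.08	-0.12	0.20
Setd1b	5.82E-03	0.13	-0.07	0.20
Dtl	1.26E-03	-0.10	0.09	0.20
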