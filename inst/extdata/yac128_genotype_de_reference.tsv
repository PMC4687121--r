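gene	direction	p	log2fc	abs_fc
Phex	down	1.13E-05	-0.645	1.564
Gm501	down	5.08E-05	-0.494	1.408
Plk5	down	5.08E-05	-0.448	1.364
Galnt13	down	1.76E-04	-0.442	1.359
Actn2	down	1.96E-04	-0.765	1.699
Dgat2l6	down	1.96E-04	-0.311	1.240
Sec14l3	down	2.30E-04	-0.413	1.332
Odf4	down	2.67E-04	-0.384	1.305
Ptprv	down	9.42E-04	-0.322	1.250
Ddit4l	down	1.53E-03	-0.407	1.326
Ryr1	down	1.80E-03	-0.577	1.492
Npl	down	2.05E-03	-0.277	1.212
Cdc2l6	down	2.16E-03	-0.278	1.213
Krt9	down	2.72E-03	-0.393	1.313
Hvcn1	down	2.72E-03	-0.229	1.172
Aoah	down	4.47E-03	-0.197	1.146
Bmp2	down	4.57E-03	-0.286	1.219
Clspn	down	5.34E-03	-0.355	1.279
Kcnk13	down	8.57E-03	-0.164	1.120
Glul	down	9.47E-03	-0.170	1.125
Pkp2	down	1.02E-02	-0.282	1.216
Oprk1	down	1.48E-02	-0.456	1.372
Cnr1	down	1.48E-02	-0.452	1.368
Gpr155	down	1.48E-02	-0.329	1.256
Zfp180	down	1.55E-02	-0.216	1.161
Vrk1	down	1.93E-02	-0.243	1.184
Farp2	down	2.05E-02	-0.154	1.112
Il33	down	2.10E-02	-0.398	1.318
Tspan2	down	2.17E-02	-0.327	1.255
Scn4b	down	2.20E-02	-0.537	1.451
Sbsn	down	2.20E-02	-0.183	1.135
Ube2cbp	down	2.20E-02	-0.156	1.114
Ppp1r9b	down	2.20E-02	-0.148	1.108
Fn3k	down	2.20E-02	-0.143	1.104
Gpx6	down	2.24E-02	-0.652	1.571
Erbb2ip	down	2.24E-02	-0.205	1.153
Lrrk2	down	3.02E-02	-0.372	1.294
Ppp1r9a	down	3.21E-02	-0.265	1.201
Traip	down	3.82E-02	-0.256	1.195
Slc1a2	down	4.13E-02	-0.141	1.103
Bank1	down	4.21E-02	-0.240	1.181
Rnf8	down	4.72E-02	-0.116	1.084
Tmc3	up	1.30E-04	0.480	1.395
Polr2a	up	2.30E-04	0.288	1.221
Il17rb	up	9.51E-04	0.238	1.179
Fat1	up	1.27E-03	0.277	1.212
Ppia	up	2.16E-03	0.188	1.139
Lrrn3	up	2.16E-03	0.280	1.214
Chdh	up	4.11E-03	0.181	1.134
Acy3	up	4.57E-03	0.292	1.224
Stat1	up	7.72E-03	0.203	1.151
Smoc1	up	1.61E-02	0.265	1.202
Rnf122	up	2.05E-02	0.186	1.138
Cited2	up	2.05E-02	0.246	1.186
Enpp6	up	2.05E-02	0.365	1.288
Spata5	up	2.29E-02	0.177	1.131
Htr2a	up	2.58E-02	0.362	1.285
Arsb	up	2.61E-02	0.176	1.130
Grhpr	up	3.21E-02	0.188	1.139
Zfp488	up	3.55E-02	0.236	1.178
Pla2g4a	up	3.55E-02	0.253	1.191
Pou6f2	up	4.02E-02	0.170	1.125
Eya1	up	4.21E-02	0.246	1.186
Ifit1	up	4.21E-02	0.383	1.304
Nfe2l3	up	4.27E-02	0.169	1.125
Plekhh2	up	4.72E-02	0.200	1.148
Mobkl2b	up	4.82E-02	0.225	1.169
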