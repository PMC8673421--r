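SYNPW001	synthetic pathway 1	G0340	G0114	G0102	G0047	G0236	G0145	G0342	G0227	G0001	G0424	G0458	G0049	G0311	G0319	G0428	G0129	G0062	G0408
SYNPW002	synthetic pathway 2	G0396	G0188	G0337	G0213	G0314	G0419	G0174	G0398	G0420	G0272	G0377	G0466	G0065	G0036	G0356	G0237	G0226	G0027	G0441	G0476	G0352
SYNPW003	synthetic pathway 3	G0113	G0245	G0157	G0414	G0203	G0380	G0025	G0253	G0012	G0213	G0089	G0407	G0040	G0335	G0108
SYNPW004	synthetic pathway 4	G0472	G0192	G0498	G0073	G0034	G0316	G0398	G0493
SYNPW005	synthetic pathway 5	G0338	G0165	G0141	G0488	G0422	G0397	G0146	G0299	G0194	G0202	G0107	G0089	G0250	G0392	G0098	G0179	G0131	G0319	G0419	G0184	G0453	G0318	G0210	G0401	G0417	G0090	G0009
SYNPW006	synthetic pathway 6	G0458	G0218	G0232	G0325	G0175	G0222	G0451	G0213	G0223	G0066	G0478	G0449	G0203	G0269	G0417	G0479	G0004	G0252	G0273	G0386	G0264	G0131	G0047	G0365
SYNPW007	synthetic pathway 7	G0496	G0073	G0441	G0168	G0101	G0473	G0394	G0022	G0351	G0112	G0457
SYNPW008	synthetic pathway 8	G0079	G0148	G0024	G0119	G0371	G0441	G0048	G0041	G0462	G0324	G0201	G0053	G0155	G0118	G0226	G0308	G0288	G0143	G0030	G0316	G0490	G0412	G0152	G0198	G0366	G0157	G0381	G0049	G0218	G0074	G0099	G0038	G0121
SYNPW009	synthetic pathway 9	G0188	G0294	G0305	G0178	G0179	G0022	G0237	G0244	G0274	G0194	G0285	G0113	G0494	G0077	G0180	G0251	G0013	G0447	G0182	G0185	G0104	G0061	G0228	G0499	G0168	G0076	G0258	G0072	G0448	G0314	G0464	G0253
SYNPW010	synthetic pathway 10	G0027	G0384	G0457	G0117	G0197	G0377	G0500	G0147
SYNPW011	synthetic pathway 11	G0410	G0407	G0081	G0261	G0097	G0490	G0123	G0324	G0428	G0167	G0484	G0357	G0481	G0143	G0208	G0061	G0452	G0267	G0180	G0196	G0024	G0201	G0195	G0328	G0455	G0063	G0275	G0388	G0333	G0158	G0288	G0412	G0092	G0006	G0136
SYNPW012	synthetic pathway 12	G0375	G0050	G0132	G0122	G0306	G0486	G0268	G0464	G0189	G0082
SYNPW013	synthetic pathway 13	G0423	G0027	G0012	G0462	G0454	G0341	G0274	G0159	G0470	G0474	G0478	G0240	G0101	G0370	G0379	G0065	G0446	G0128	G0196	G0020	G0014	G0333	G0324	G0289	G0132	G0112	G0142	G0210	G0002	G0003	G0154	G0371	G0011	G0088	G0386	G0174	G0491	G0388	G0099	G0418	G0331	G0247
SYNPW014	synthetic pathway 14	G0350	G0180	G0090	G0260	G0133	G0230	G0361	G0181	G0392	G0340	G0291	G0267	G0155	G0167	G0288	G0442	G0499	G0074	G0469	G0191	G0289	G0071	G0364	G0013	G0421	G0047	G0166	G0178	G0172	G0307	G0128	G0102	G0232
SYNPW015	synthetic pathway 15	G0063	G0443	G0258	G0375	G0165	G0213	G0276	G0093
SYNPW016	synthetic pathway 16	G0390	G0336	G0023	G0419	G0451	G0320	G0334	G0286	G0158	G0498	G0297	G0067	G0122	G0447	G0057	G0159	G0092	G0175	G0176	G0047	G0219	G0212	G0457	G0221	G0040	G0315	G0246	G0471	G0132	G0048	G0161	G0068
SYNPW017	synthetic pathway 17	G0059	G0346	G0180	G0298	G0314	G0410	G0060	G0289	G0037	G0265	G0372	G0109	G0056	G0046	G0155	G0367	G0073	G0011	G0337	G0094	G0493	G0286	G0403	G0446	G0442	G0476	G0088	G0376	G0408	G0464	G0054	G0187	G0023	G0389	G0303	G0136	G0107	G0440	G0414	G0384	G0404	G0116
SYNPW018	synthetic pathway 18	G0059	G0196	G0167	G0112	G0324	G0108	G0261	G0133	G0317	G0119	G0249	G0337	G0162	G0351	G0356	G0171	G0373	G0340	G0129	G0063	G0024	G0384	G0017	G0168	G0481	G0182	G0034	G0429	G0166	G0290	G0357	G0136	G0124	G0098	G0161	G0191	G0236	G0029	G0016	G0094	G0345	G0093	G0336	G0306	G0349	G0263	G0406	G0486	G0410	G0071
SYNPW019	synthetic pathway 19	G0181	G0309	G0323	G0317	G0048	G0272	G0223	G0360	G0016	G0109	G0420	G0075	G0231	G0059	G0127	G0250	G0482	G0217	G0124	G0028	G0161	G0219	G0046	G0040	G0446	G0011	G0042	G0196	G0123	G0165	G0085	G0268	G0208	G0422	G0409	G0390	G0359	G0112	G0406	G0079	G0058	G0286	G0008	G0220	G0282
SYNPW020	synthetic pathway 20	G0067	G0384	G0150	G0075	G0032	G0228	G0091	G0141	G0123	G0038	G0430	G0095	G0018	G0376	G0495	G0057	G0204	G0499	G0370	G0418	G0331	G0303
SYNPW021	synthetic pathway 21	G0244	G0411	G0419	G0126	G0479	G0354	G0146	G0190	G0287	G0108	G0181	G0149	G0325	G0173	G0096	G0094	G0333	G0097	G0421	G0454	G0398	G0062	G0336	G0055	G0462	G0204	G0457	G0275	G0128	G0366	G0165	G0015	G0078	G0418	G0455	G0451	G0261	G0308	G0423	G0378	G0119	G0005	G0264
SYNPW022	synthetic pathway 22	G0006	G0188	G0018	G0329	G0186	G0256	G0213	G0237	G0155	G0178	G0433	G0001	G0439	G0230	G0068	G0200	G0037	G0229	G0004	G0326
SYNPW023	synthetic pathway 23	G0372	G0477	G0455	G0392	G0377	G0434	G0037	G0202	G0269	G0121	G0321	G0298	G0291	G0234	G0152	G0311	G0094	G0463	G0374	G0039	G0072	G0016	G0004	G0118	G0150	G0330	G0300	G0483	G0482	G0493	G0479	G0449	G0296	G0181	G0373	G0336	G0043	G0390	G0316	G0271	G0461	G0475	G0175	G0274	G0445	G0201	G0287	G0303	G0333	G0396
SYNPW024	synthetic pathway 24	G0476	G0438	G0495	G0195	G0488	G0127	G0375	G0445	G0190	G0325	G0213	G0424	G0340	G0229	G0023	G0416	G0063	G0211	G0499	G0115	G0409	G0087	G0405	G0114	G0007	G0153	G0297	G0010	G0118	G0174	G0425	G0295	G0483	G0048	G0121	G0187	G0392	G0347	G0426	G0486	G0408	G0226	G0083	G0074	G0311	G0122	G0255	G0149	G0314
SYNPW_PLANTED	synthetic planted resistance module	G0001	G0002	G0003	G0004	G0005	G0006	G0007	G0008	G0009	G0010	G0011	G0012	G0013	G0014	G0015	G0016	G0017	G0018	G0019	G0020	G0389	G0252	G0257	G0190	G0343	G0180	G0121	G0382	G0247	G0476	G0351	G0224	G0342	G0142	G0174
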