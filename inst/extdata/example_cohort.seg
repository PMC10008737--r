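sample	chrom	start	end	cn
S0001	chr1	1	125013880	2
S0001	chr1	125013881	134855064	1
S0001	chr1	134855065	171555595	2
S0001	chr1	171555596	180276109	1
S0001	chr1	180276110	2e+08	2
S0001	chr2	1	19318030	2
S0001	chr2	19318031	22718412	3
S0001	chr2	22718413	79642721	2
S0001	chr2	79642722	86731802	1
S0001	chr2	86731803	124195294	2
S0001	chr2	124195295	127513897	3
S0001	chr2	127513898	139838236	2
S0001	chr2	139838237	144606552	3
S0001	chr2	144606553	1.8e+08	2
S0001	chr3	1	1.6e+08	2
S0001	chr4	1	17484481	2
S0001	chr4	17484482	26123865	3
S0001	chr4	26123866	1.4e+08	2
S0001	chr5	1	1.2e+08	2
S0001	chr6	1	1e+08	2
S0001	chr7	1	27447310	2
S0001	chr7	27447311	36374926	1
S0001	chr7	36374927	9e+07	2
S0001	chr8	1	6549389	2
S0001	chr8	6549390	11031923	1
S0001	chr8	11031924	47821849	2
S0001	chr8	47821850	51898943	1
S0001	chr8	51898944	63269237	2
S0001	chr8	63269238	72602277	3
S0001	chr8	72602278	8e+07	2
S0001	chrX	1	19348871	2
S0001	chrX	19348872	21556341	1
S0001	chrX	21556342	112543571	2
S0001	chrX	112543572	116453051	1
S0001	chrX	116453052	1.5e+08	2
S0002	chr1	1	73251847	2
S0002	chr1	73251848	82068633	3
S0002	chr1	82068634	2e+08	2
S0002	chr2	1	1.8e+08	2
S0002	chr3	1	1.6e+08	2
S0002	chr4	1	56502454	2
S0002	chr4	56502455	59032918	1
S0002	chr4	59032919	76348267	2
S0002	chr4	76348268	76932218	3
S0002	chr4	76932219	79204147	2
S0002	chr4	79204148	80499580	3
S0002	chr4	80499581	91382035	2
S0002	chr4	91382036	91549631	3
S0002	chr4	91549632	92070917	2
S0002	chr4	92070918	96366370	3
S0002	chr4	96366371	99353137	2
S0002	chr4	99353138	100695947	3
S0002	chr4	100695948	101567225	2
S0002	chr4	101567226	101617861	3
S0002	chr4	101617862	102877980	2
S0002	chr4	102877981	103367587	3
S0002	chr4	103367588	103646999	2
S0002	chr4	103647000	103967545	3
S0002	chr4	103967546	104364274	2
S0002	chr4	104364275	108611451	3
S0002	chr4	108611452	109744317	2
S0002	chr4	109744318	110652649	3
S0002	chr4	110652650	1.4e+08	2
S0002	chr5	1	55896681	2
S0002	chr5	55896682	64007165	1
S0002	chr5	64007166	1.2e+08	2
S0002	chr6	1	45181383	2
S0002	chr6	45181384	49679617	1
S0002	chr6	49679618	1e+08	2
S0002	chr7	1	9e+07	2
S0002	chr8	1	8e+07	2
S0002	chrX	1	33721213	2
S0002	chrX	33721214	36795620	3
S0002	chrX	36795621	1.5e+08	2
S0003	chr1	1	17664288	2
S0003	chr1	17664289	27041765	3
S0003	chr1	27041766	54068717	2
S0003	chr1	54068718	57489440	1
S0003	chr1	57489441	156281287	2
S0003	chr1	156281288	158708926	3
S0003	chr1	158708927	189735749	2
S0003	chr1	189735750	196656362	1
S0003	chr1	196656363	2e+08	2
S0003	chr2	1	99594186	2
S0003	chr2	99594187	101515291	1
S0003	chr2	101515292	140489367	2
S0003	chr2	140489368	145711698	3
S0003	chr2	145711699	1.8e+08	2
S0003	chr3	1	90204288	2
S0003	chr3	90204289	96206680	1
S0003	chr3	96206681	99192745	2
S0003	chr3	99192746	105819376	1
S0003	chr3	105819377	142086265	2
S0003	chr3	142086266	143391473	1
S0003	chr3	143391474	1.6e+08	2
S0003	chr4	1	58315342	2
S0003	chr4	58315343	68131915	1
S0003	chr4	68131916	80051993	2
S0003	chr4	80051994	86618471	1
S0003	chr4	86618472	103605941	2
S0003	chr4	103605942	108926685	1
S0003	chr4	108926686	1.4e+08	2
S0003	chr5	1	14712912	2
S0003	chr5	14712913	17359213	1
S0003	chr5	17359214	72402969	2
S0003	chr5	72402970	73177586	3
S0003	chr5	73177587	75931429	2
S0003	chr5	75931430	79618919	3
S0003	chr5	79618920	81271477	2
S0003	chr5	81271478	86686604	3
S0003	chr5	86686605	89039383	2
S0003	chr5	89039384	93525135	3
S0003	chr5	93525136	93756869	2
S0003	chr5	93756870	96282934	3
S0003	chr5	96282935	97300798	2
S0003	chr5	97300799	97381402	3
S0003	chr5	97381403	99228714	2
S0003	chr5	99228715	100904957	3
S0003	chr5	100904958	101025021	2
S0003	chr5	101025022	101509781	3
S0003	chr5	101509782	103675731	2
S0003	chr5	103675732	105227855	3
S0003	chr5	105227856	108612977	2
S0003	chr5	108612978	109598194	3
S0003	chr5	109598195	1.2e+08	2
S0003	chr6	1	166534	2
S0003	chr6	166535	4754022	1
S0003	chr6	4754023	1e+08	2
S0003	chr7	1	9e+07	2
S0003	chr8	1	2490689	2
S0003	chr8	2490690	11790937	3
S0003	chr8	11790938	8e+07	2
S0003	chrX	1	56157802	2
S0003	chrX	56157803	61746832	1
S0003	chrX	61746833	84855405	2
S0003	chrX	84855406	93203179	1
S0003	chrX	93203180	1.5e+08	2
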