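time_d	substrate_uM	co2_uM
0	335.90386830054786	0
1	278.1876125066819	5.634648330033369
2	281.1126547144854	11.593777658564173
3	280.89484050355014	17.251721253747004
4	269.07445330769787	21.26161336245659
5	265.2930819527918	27.53269416056504
6	284.2894605229822	32.071729542167894
7	267.99249289699605	40.51021216037656
8	267.29985875087823	44.91184549349907
9	291.153696235007	50.0506020558549
10	261.29912282980473	54.66942196349478
11	289.0811312638931	59.712260554635876
12	278.0478739368714	70.42033275028628
13	247.77484540348124	68.68001058946965
14	263.30182134164903	77.60859843517318
15	240.76753999552747	85.0739572203406
16	220.82544638184444	94.93657791948303
17	223.16337526654027	91.65212511491572
18	222.26870395386823	99.07130814054882
19	229.06348507797043	99.34842573405031
20	222.8923425780852	109.50001668913835
21	216.95166292282906	114.91462770392813
22	218.97735818987744	131.4014357896382
23	187.39100357089993	132.2595281490407
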