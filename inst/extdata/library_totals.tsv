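cultivar	year	week	replicate1	replicate2	replicate3	combined
Desiree	2008	9	826191	1661343	973030	3460564
Desiree	2008	12	411461	NA	892609	1304070
Desiree	2008	15	278536	885199	904277	2068012
Desiree	2008	18	1049772	1277006	NA	2326778
Desiree	2008	21	586672	983331	1052849	2622852
Desiree	2009	9	7644714	11630251	9769669	29044634
Desiree	2009	11	16693106	12714866	10440036	39848008
Jutlandia	2008	9	NA	533883	1433784	1967667
Jutlandia	2008	12	1133434	852047	1044402	3029883
Jutlandia	2008	15	1050297	761643	698728	2510668
Jutlandia	2008	18	578588	1095558	1291794	2965940
Jutlandia	2008	21	NA	607322	838688	1446010
Jutlandia	2009	9	15674527	13134880	9724414	38533821
Jutlandia	2009	11	17166126	10144737	12100324	39411187
Kuras	2008	9	1109293	1988857	2368777	5466927
Kuras	2008	12	970045	1034725	513293	2518063
Kuras	2008	15	796137	213351	NA	1009488
Kuras	2008	18	457545	1116289	921391	2495225
Kuras	2008	21	393784	463443	287787	1145014
Kuras	2009	9	12593044	12071757	12555532	37220333
Kuras	2009	11	10970940	67110212	8743707	86824859
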