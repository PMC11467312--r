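id,age,sex,lesion_age_weeks,lesion_volume_mm3,stroke_type,group
1,60,M,8,NA,I,subacute
2,69,M,21,56011,I,subacute
3,74,M,6,NA,I,subacute
4,78,M,24,3740,I,subacute
5,78,M,5,NA,I,subacute
6,51,M,12,42429,I,subacute
7,74,M,6,37303,I,subacute
8,59,M,15,22798,I,subacute
9,71,M,20,140928,I,subacute
10,64,M,10,84121,I,subacute
11,46,M,18,17216,I,subacute
12,48,M,9,45655,I,subacute
13,48,F,20,NA,I,subacute
14,58,M,169,53182,I,chronic
15,40,M,73,95664,I,chronic
16,60,M,81,73481,I,chronic
17,67,M,70,195985,I,chronic
18,43,M,49,121210,I,chronic
19,62,M,33,76228,H,chronic
20,58,F,72,93033,I,chronic
21,54,F,194,103136,I,chronic
22,62,F,31,56184,I,chronic
23,51,F,37,44781,H,chronic
24,75,F,47,NA,I,chronic
25,44,F,25,98472,I,chronic
26,49,F,96,71275,I,chronic
27,72,F,114,111584,I,chronic
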