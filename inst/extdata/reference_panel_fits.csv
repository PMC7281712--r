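cell_line,drug,hill_rmse,i_max_pct,ic50_star_nM,hill_n,biphasic_rmse,f1_pct,f2_pct,kd1_nM,kd2_uM,target
HT-29,AZD-6244,0.027,73,248,0.52,0.029,55,45,92,54.1,Mek
HT-29,BMS-754807,0.023,100,585,0.34,0.047,44,56,12,8.4,IGF-1R
HT-29,Dasatinib,0.032,67,147,0.62,0.026,51,49,59,33.3,Src
HT-29,HG6-64-1,0.024,51,16,0.84,0.026,50,50,14,>100,BRAF
SK-CO-1,AZD-6244,0.025,83,543,0.69,0.025,55,45,169,13.6,Mek
SK-CO-1,BMS-754807,0.034,68,200,0.5,0.048,44,56,32,29.3,IGF-1R
NCI-H747,AZD-6244,0.019,75,71,0.62,0.029,61,39,34,25.6,Mek
NCI-H747,BMS-754807,0.028,75,231,0.6,0.031,54,46,75,22.4,IGF-1R
MDA-MB-231,AZD-6244,0.021,46,210,0.68,0.023,36,64,91,>100,Mek
MDA-MB-231,Dasatinib,0.05,88,300,0.49,0.018,49,51,30,9.3,Src
MDA-MB-468,GSK690693,0.08,100,2940,0.42,0.06,37,63,67,15.6,Akt
MDA-MB-468,Lapatinib,0.026,100,190,0.45,0.038,53,47,17,3.1,EGFR
HCC-827,Gefitinib,0.027,89,10,1.73,0.056,92,8,11,>100,EGFR
HCC-827,Erlotinib,0.029,90,14,1.87,0.062,93,7,16,>100,EGFR
HCC-827,Dasatinib,0.049,93,149,1.88,0.075,98,2,157,>100,Src
CTV-1,Bosutinib,0.033,96,51,2.71,0.1,100,0,56,None,Src
CTV-1,Dasatinib,0.043,97,9.1,2.72,0.11,100,0,9.1,None,Src
CTV-1,WH-4-023,0.043,98,712,2.49,0.096,100,0,716,None,Src
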