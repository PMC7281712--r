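cell_line,drug,hill_rmse,i_max_pct,ic50_star_nM,hill_n,biphasic_rmse,f1_pct,f2_pct,kd1_nM,kd2_uM,target
DU-4475,AZ628,0.011,91,27,1.81,0.055,95,5,26,3469,BRAF
DU-4475,PLX4720,0.035,90,378,1.41,0.052,98,2,472,32448,BRAF
DU-4475,SB590885,0.081,75,353,1.47,0.088,86,14,524,60,BRAF
DU-4475,RDEA119,0.030,86,37,1.62,0.055,90,10,37,75644,Mek
DU-4475,CI-1040,0.024,88,116,1.63,0.054,93,7,131,50525,Mek
DU-4475,PD-0325901,0.044,81,2.4,2.30,0.094,87,13,2.6,2169,Mek
DU-4475,VX-11e,0.029,98,80,1.36,0.049,100,0,80,None,Erk
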