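model,row,element_group,smirks,epsilon_kcal_mol,rmin_half_A
HCON,1,Hydrogen,[#1:1]-[#6X4],0.017,1.27
HCON,2,Hydrogen,[#1:1]-[#6X3],0.017,1.27
HCON,3,Hydrogen,[#1:1]-[#7],0.017,1.27
HCON,4,Hydrogen,[#1:1]-[#8],0.017,1.27
HCON,5,Carbon,[#6:1],0.074,2.11
HCON,6,Carbon,[#6X4:1],0.074,2.11
HCON,7,Carbon,[#6X2:1],0.074,2.11
HCON,8,Nitrogen,[#7X3:1],0.194,1.47
HCON,9,Nitrogen,[#7:1],0.194,1.47
HCON,10,Oxygen,[#8:1],0.220,1.11
HCON,11,Oxygen,[#8X2H1+0:1],0.220,1.11
HCON,12,Oxygen,[#8X2H0+0:1],0.220,1.11
HCO3N,1,Hydrogen,[#1:1]-[#6X4],0.034,1.42
HCO3N,2,Hydrogen,[#1:1]-[#6X3],0.034,1.42
HCO3N,3,Hydrogen,[#1:1]-[#7],0.034,1.42
HCO3N,4,Hydrogen,[#1:1]-[#8],0.034,1.42
HCO3N,5,Carbon,[#6:1],0.077,1.84
HCO3N,6,Carbon,[#6X4:1],0.077,1.84
HCO3N,7,Carbon,[#6X2:1],0.077,1.84
HCO3N,8,Nitrogen,[#7X3:1],0.231,1.79
HCO3N,9,Nitrogen,[#7:1],0.231,1.79
HCO3N,10,Oxygen,[#8:1],0.137,1.73
HCO3N,11,Oxygen,[#8X2H1+0:1],0.494,1.89
HCO3N,12,Oxygen,[#8X2H0+0:1],0.087,1.82
H2CON,1,Hydrogen,[#1:1]-[#6X4],0.014,1.39
H2CON,2,Hydrogen,[#1:1]-[#6X3],0.014,1.39
H2CON,3,Hydrogen,[#1:1]-[#7],0.015,0.69
H2CON,4,Hydrogen,[#1:1]-[#8],0.015,0.69
H2CON,5,Carbon,[#6:1],0.081,2.06
H2CON,6,Carbon,[#6X4:1],0.081,2.06
H2CON,7,Carbon,[#6X2:1],0.081,2.06
H2CON,8,Nitrogen,[#7X3:1],0.177,1.80
H2CON,9,Nitrogen,[#7:1],0.177,1.80
H2CON,10,Oxygen,[#8:1],0.205,1.61
H2CON,11,Oxygen,[#8X2H1+0:1],0.205,1.61
H2CON,12,Oxygen,[#8X2H0+0:1],0.205,1.61
H2CO3N,1,Hydrogen,[#1:1]-[#6X4],0.023,1.42
H2CO3N,2,Hydrogen,[#1:1]-[#6X3],0.023,1.42
H2CO3N,3,Hydrogen,[#1:1]-[#7],0.007,0.88
H2CO3N,4,Hydrogen,[#1:1]-[#8],0.007,0.88
H2CO3N,5,Carbon,[#6:1],0.078,1.96
H2CO3N,6,Carbon,[#6X4:1],0.078,1.96
H2CO3N,7,Carbon,[#6X2:1],0.078,1.96
H2CO3N,8,Nitrogen,[#7X3:1],0.210,1.83
H2CO3N,9,Nitrogen,[#7:1],0.210,1.83
H2CO3N,10,Oxygen,[#8:1],0.197,1.71
H2CO3N,11,Oxygen,[#8X2H1+0:1],0.218,1.60
H2CO3N,12,Oxygen,[#8X2H0+0:1],0.151,1.59
H2CO3Nreopt,1,Hydrogen,[#1:1]-[#6X4],0.030,1.42
H2CO3Nreopt,2,Hydrogen,[#1:1]-[#6X3],0.030,1.42
H2CO3Nreopt,3,Hydrogen,[#1:1]-[#7],0.031,1.44
H2CO3Nreopt,4,Hydrogen,[#1:1]-[#8],0.031,1.44
H2CO3Nreopt,5,Carbon,[#6:1],0.078,1.87
H2CO3Nreopt,6,Carbon,[#6X4:1],0.078,1.87
H2CO3Nreopt,7,Carbon,[#6X2:1],0.078,1.87
H2CO3Nreopt,8,Nitrogen,[#7X3:1],0.245,1.78
H2CO3Nreopt,9,Nitrogen,[#7:1],0.245,1.78
H2CO3Nreopt,10,Oxygen,[#8:1],0.100,1.65
H2CO3Nreopt,11,Oxygen,[#8X2H1+0:1],0.533,1.87
H2CO3Nreopt,12,Oxygen,[#8X2H0+0:1],0.096,1.82
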