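organ,volume_per_kg,flow_per_kg,f_water,f_lipid,f_protein
arterial_blood,0.025,8.60,0.81,0.003,0.18
venous_blood,0.060,8.60,0.81,0.003,0.18
muscle,0.450,1.10,0.76,0.022,0.17
adipose,0.150,0.25,0.15,0.800,0.03
kidney,0.005,1.50,0.78,0.020,0.16
liver,0.030,2.70,0.74,0.040,0.18
rest,0.280,3.05,0.72,0.040,0.18
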