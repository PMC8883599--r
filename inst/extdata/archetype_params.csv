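archetype,share,is_beverage,consume_prob,amount_meanlog,amount_sdlog,cost_lo,cost_hi,racc_lo,racc_hi,protein_lo,protein_hi,calcium_lo,calcium_hi,choline_lo,choline_hi,fibre_lo,fibre_hi,iron_lo,iron_hi,magnesium_lo,magnesium_hi,potassium_lo,potassium_hi,vit_a_lo,vit_a_hi,vit_c_lo,vit_c_hi,vit_d_lo,vit_d_hi,vit_e_lo,vit_e_hi,energy_lo,energy_hi,sodium_lo,sodium_hi,added_sugars_lo,added_sugars_hi,sat_fat_lo,sat_fat_hi
staple,0.47,FALSE,0.60,4.4998,0.6,0.25,0.70,50,140,7,13,80,200,10,25,2,8,2,5,20,60,100,250,0,10,0,1,0,0.1,0.2,1,900,1500,300,600,1,8,0.5,3
fortified_cereal,0.08,FALSE,0.30,3.9120,0.5,0.60,1.20,30,55,6,12,300,700,10,30,5,12,10,30,60,140,200,400,300,600,15,60,2,5,3,9,1500,1700,400,700,20,40,0.5,2
fish,0.08,FALSE,0.15,4.7005,0.5,1.20,3.00,85,140,18,26,10,350,60,100,0,0.1,0.5,2,25,60,300,500,10,100,0,2,5,15,0.5,2,400,900,300,600,0,0.5,0.5,3
leafy_green,0.12,FALSE,0.25,4.3820,0.7,0.40,1.20,85,85,2,4,80,180,15,35,2,4.5,1,3.5,30,90,350,600,200,500,25,90,0,0.01,1,3,80,200,20,120,0,0.5,0,0.3
juice,0.08,TRUE,0.30,5.4806,0.5,0.10,0.30,240,240,0.5,1,100,160,5,10,0.1,0.5,0.1,0.5,10,15,150,220,0,10,30,60,0.8,1.5,0.04,0.3,170,230,0,10,0,2,0,0.05
nutrition_bar,0.06,FALSE,0.08,3.8067,0.4,1.00,2.20,40,40,15,30,200,600,20,60,5,15,4,12,80,200,250,500,200,700,30,120,1,4,5,15,1400,1900,200,500,15,35,3,8
water_like,0.06,TRUE,0.75,6.2146,0.8,0.0005,0.01,240,360,0,0.1,1,5,0,0.4,0,0,0,0.02,0.5,3,0,6,0,0,0,0,0,0,0,0,0,6,1,5,0,0,0,0
milk_substitute,0.05,TRUE,0.05,5.4806,0.4,0.20,0.50,240,240,1,3.5,100,140,5,9,0.2,1,0.1,0.5,5,16,30,80,40,70,0,1,0.9,1.3,0.5,4,100,260,30,80,0,6,0,1.5
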