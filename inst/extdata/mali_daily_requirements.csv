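nutrient,amount_per_day,unit
energy,2615.20,kcal
protein,64.00,g
carbohydrate,65.00,g
fat,58.12,g
lys,3.26,g
leu,3.52,g
val,2.05,g
his,1.15,g
trp,0.45,g
thr,1.73,g
ile,1.60,g
met_cys,1.60,g
phe_tyr,3.01,g
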