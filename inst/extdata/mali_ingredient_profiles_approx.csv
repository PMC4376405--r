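name,notes,basis,protein,fat,ash,fiber,carbohydrate,energy,moisture,lys,leu,val,his,trp,thr,ile,met,cys,phe,tyr
corn,"whole grain; reference approximation",as_is,9.4,4.7,1.2,7.3,67.0,365,10.4,0.26,1.16,0.45,0.29,0.07,0.35,0.34,0.20,0.17,0.46,0.38
sorghum,"whole grain; reference approximation",as_is,11.3,3.3,1.6,6.3,68.3,339,9.2,0.23,1.49,0.56,0.25,0.12,0.35,0.43,0.17,0.13,0.55,0.32
peanuts,"raw, all types; roasted form used in products; reference approximation",as_is,25.8,49.2,2.3,8.5,7.7,567,6.5,0.93,1.67,1.08,0.65,0.25,0.88,0.91,0.32,0.33,1.34,1.05
millet,"whole grain; flour form used in products; reference approximation",as_is,11.0,4.2,3.3,8.5,64.3,378,8.7,0.21,1.40,0.58,0.24,0.12,0.35,0.47,0.22,0.21,0.58,0.34
fonio,"whole grain; reference approximation",as_is,9.0,1.8,3.4,3.3,70.1,341,12.4,0.25,0.90,0.50,0.20,0.15,0.32,0.38,0.45,0.25,0.48,0.30
cassava,"raw root; reference approximation",as_is,1.4,0.3,0.6,1.8,36.2,160,59.7,0.04,0.04,0.03,0.02,0.02,0.03,0.03,0.01,0.03,0.03,0.02
cowpeas,"raw, mature seeds; decorticated form used in products; reference approximation",as_is,23.5,1.3,3.2,10.6,49.4,336,12.0,1.59,1.80,1.12,0.73,0.29,0.90,0.96,0.34,0.26,1.37,0.71
rice,"white, raw; used as koji at fixed levels; reference approximation",as_is,7.1,0.7,0.6,1.3,78.7,365,11.6,0.26,0.59,0.44,0.17,0.08,0.26,0.31,0.17,0.15,0.38,0.24
barley,"hulled, raw; used as koji at fixed levels; reference approximation",as_is,12.5,2.3,2.3,17.3,56.2,354,9.4,0.47,0.85,0.61,0.28,0.21,0.42,0.46,0.24,0.28,0.70,0.36
yam,"raw tuber; reference approximation",as_is,1.5,0.2,0.8,4.1,23.8,118,69.6,0.06,0.10,0.07,0.03,0.02,0.05,0.06,0.02,0.02,0.07,0.04
sugar,"granulated; reference approximation",as_is,0.0,0.0,0.0,0.0,99.98,387,0.02,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00,0.00
sesame,"whole, dried seeds; reference approximation",as_is,17.7,49.7,4.5,11.8,11.6,573,4.7,0.57,1.36,0.99,0.52,0.39,0.74,0.76,0.59,0.36,0.94,0.74
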