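nutrient,product,predicted,actual,published_difference
protein,A,17.6,19.5,1.86
protein,B,17.3,19.3,1.95
protein,C,17.1,18.5,1.45
protein,D,17.8,19.8,2.04
protein,E,17.7,19.6,1.92
protein,F,17.6,19.6,1.99
fat,A,20.0,19.3,-0.68
fat,B,20.0,19.1,-0.88
fat,C,20.0,19.2,-0.86
fat,D,20.0,19.8,-0.19
fat,E,20.0,19.8,-0.18
fat,F,20.0,19.6,-0.43
ash,A,2.25,2.95,0.70
ash,B,2.06,2.81,0.75
ash,C,1.87,2.76,0.89
ash,D,2.34,2.94,0.60
ash,E,2.23,2.91,0.68
ash,F,2.12,2.89,0.77
fiber,A,7.18,6.90,-0.28
fiber,B,6.58,6.42,-0.16
fiber,C,5.97,6.46,0.49
fiber,D,8.13,6.07,-2.06
fiber,E,8.47,7.16,-1.31
fiber,F,8.81,7.89,-0.92
carbohydrate,A,52.5,51.3,-1.13
carbohydrate,B,52.7,52.4,-0.32
carbohydrate,C,52.9,53.1,0.25
carbohydrate,D,52.4,51.3,-1.10
carbohydrate,E,52.6,50.5,-2.12
carbohydrate,F,52.8,50.1,-2.72
energy,A,441,457,16.0
energy,B,441,459,17.5
energy,C,441,459,17.7
energy,D,441,463,22.2
energy,E,440,459,18.4
energy,F,440,455,14.8
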