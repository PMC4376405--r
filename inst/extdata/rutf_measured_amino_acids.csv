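nutrient,product,predicted,actual,published_difference
lys,A,0.77,0.59,-0.17
leu,A,1.34,1.42,0.08
val,A,0.80,0.82,0.02
his,A,0.47,0.41,-0.06
trp,A,0.19,0.20,0.01
thr,A,0.62,0.58,-0.04
ile,A,0.67,0.71,0.05
met,A,0.25,0.27,0.02
cys,A,0.23,0.21,-0.03
met_cys,A,0.48,0.47,-0.01
phe,A,0.95,1.00,0.05
tyr,A,0.65,0.76,0.11
phe_tyr,A,1.60,1.76,0.16
lys,B,0.77,0.57,-0.20
leu,B,1.28,1.34,0.06
val,B,0.79,0.79,0.01
his,B,0.46,0.40,-0.06
trp,B,0.18,0.19,0.00
thr,B,0.61,0.58,-0.03
ile,B,0.65,0.69,0.03
met,B,0.24,0.26,0.02
cys,B,0.23,0.20,-0.03
met_cys,B,0.47,0.46,-0.01
phe,B,0.94,0.98,0.04
tyr,B,0.64,0.74,0.10
phe_tyr,B,1.58,1.72,0.14
lys,C,0.77,0.52,-0.25
leu,C,1.22,1.25,0.03
val,C,0.78,0.77,-0.01
his,C,0.46,0.39,-0.07
trp,C,0.18,0.18,-0.01
thr,C,0.60,0.55,-0.05
ile,C,0.64,0.67,0.02
met,C,0.24,0.25,0.01
cys,C,0.22,0.19,-0.03
met_cys,C,0.46,0.44,-0.03
phe,C,0.92,0.94,0.02
tyr,C,0.64,0.72,0.08
phe_tyr,C,1.56,1.65,0.10
lys,D,0.77,0.56,-0.21
leu,D,1.36,1.45,0.09
val,D,0.80,0.83,0.03
his,D,0.47,0.42,-0.05
trp,D,0.19,0.19,0.00
thr,D,0.62,0.58,-0.04
ile,D,0.67,0.72,0.05
met,D,0.25,0.28,0.03
cys,D,0.24,0.21,-0.03
met_cys,D,0.49,0.49,0.00
phe,D,0.96,1.02,0.06
tyr,D,0.65,0.76,0.11
phe_tyr,D,1.61,1.78,0.17
lys,E,0.77,0.54,-0.22
leu,E,1.32,1.39,0.07
val,E,0.80,0.80,0.00
his,E,0.47,0.40,-0.07
trp,E,0.19,0.19,0.00
thr,E,0.62,0.57,-0.05
ile,E,0.66,0.71,0.04
met,E,0.25,0.26,0.01
cys,E,0.24,0.21,-0.03
met_cys,E,0.49,0.47,-0.02
phe,E,0.96,1.00,0.04
tyr,E,0.65,0.74,0.09
phe_tyr,E,1.61,1.73,0.13
lys,F,0.77,0.52,-0.25
leu,F,1.28,1.35,0.07
val,F,0.79,0.80,0.01
his,F,0.46,0.39,-0.07
trp,F,0.20,0.18,-0.01
thr,F,0.62,0.57,-0.05
ile,F,0.66,0.69,0.04
met,F,0.25,0.26,0.01
cys,F,0.24,0.21,-0.03
met_cys,F,0.49,0.47,-0.02
phe,F,0.95,0.99,0.04
tyr,F,0.62,0.74,0.10
phe_tyr,F,1.60,1.73,0.13
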