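ingredient,year,price_usd_per_kg
corn,2004,0.10
sorghum,2004,0.11
millet,2004,0.12
barley,2004,0.19
rice,2004,0.21
peanuts,2004,0.24
cowpeas,2004,0.26
yam,2004,0.34
cassava,2004,0.38
fonio,2004,0.56
sugar,2004,1.03
corn,2005,0.20
sorghum,2005,0.23
millet,2005,0.25
barley,2005,0.19
rice,2005,0.27
peanuts,2005,0.24
cowpeas,2005,0.26
yam,2005,0.63
cassava,2005,0.38
fonio,2005,0.56
sugar,2005,1.03
corn,2006,0.17
sorghum,2006,0.18
millet,2006,0.20
barley,2006,0.19
rice,2006,0.25
peanuts,2006,0.31
cowpeas,2006,0.26
yam,2006,0.63
cassava,2006,0.38
fonio,2006,0.57
sugar,2006,1.03
corn,2007,0.15
sorghum,2007,0.18
millet,2007,0.18
barley,2007,0.22
rice,2007,0.25
peanuts,2007,0.40
cowpeas,2007,0.30
yam,2007,0.31
cassava,2007,0.11
fonio,2007,0.63
sugar,2007,1.03
corn,2008,0.17
sorghum,2008,0.19
millet,2008,0.19
barley,2008,0.23
rice,2008,0.26
peanuts,2008,0.47
cowpeas,2008,0.36
yam,2008,0.28
cassava,2008,0.09
fonio,2008,0.83
sugar,2008,1.03
corn,2009,0.18
sorghum,2009,0.24
millet,2009,0.29
barley,2009,0.34
rice,2009,0.32
peanuts,2009,0.51
cowpeas,2009,0.35
yam,2009,0.23
cassava,2009,0.06
fonio,2009,0.83
sugar,2009,1.03
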