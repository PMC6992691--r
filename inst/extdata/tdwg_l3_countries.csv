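l3_code,country,iso2
ANG,Angola,AO
BER,Bermuda,BM
BOT,Botswana,BW
BZN,Brazil North,BR
CPP,South Africa,ZA
FRA,France,FR
GER,Germany,DE
GRB,Great Britain,GB
IND,India,IN
IRE,Ireland,IE
ITA,Italy,IT
KEN,Kenya,KE
MDG,Madagascar,MG
MLW,Malawi,MW
MOZ,Mozambique,MZ
NAM,Namibia,NA
NWY,Norway,NO
POR,Portugal,PT
SPA,Spain,ES
SWE,Sweden,SE
TAN,Tanzania,TZ
ZAM,Zambia,ZM
ZIM,Zimbabwe,ZW
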