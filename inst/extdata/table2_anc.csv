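unit_id,country,region_label,survey_year,sample,n_provinces,events
AGO,Angola,Central,2015,6103,18,475
BEN,Benin,West,2017,8720,12,782
BFA,Burkina Faso,West,2021,6211,13,54
BDI,Burundi,East,2016,8260,18,4118
CMR,Cameroon,Central,2018,5295,12,376
TCD,Chad,Central,2014,10601,21,3243
COM,Comoros,East,2012,1851,3,902
COD,DC Congo,Central,2013,9862,11,4656
CIV,Cote D'Ivoire,West,2021,4499,14,177
ETH,Ethiopia,East,2016,7532,11,2379
GAB,Gabon,Central,2019,3189,11,434
GMB,Gambia,West,2019,5045,8,218
GHA,Ghana,West,2022,4115,16,1589
GIN,Guinea,West,2018,5134,8,156
KEN,Kenya,East,2022,7857,47,339
LSO,Lesotho,Southern,2014,2153,10,1610
LBR,Liberia,West,2019,2948,5,811
MDG,Madagascar,East,2021,8324,23,192
MWI,Malawi,East,2015,12368,3,183
MLI,Mali,West,2018,6366,9,206
MRT,Mauritania,West,2019,7669,14,308
MOZ,Mozambique,East,2022,5120,11,95
NAM,Namibia,Southern,2013,1948,13,1259
NER,Niger,West,2012,7910,8,2593
NGA,Nigeria,West,2018,18217,6,3800
RWA,Rwanda,East,2019,5655,5,15
SEN,Senegal,West,2011,7410,14,165
SLE,Sierra Leone,West,2019,6308,5,1388
ZAF,South Africa,Southern,2016,1460,9,1097
TZA,Tanzania,East,2022,5054,30,147
TGO,Togo,West,2013,4551,6,2599
UGA,Uganda,East,2016,9568,15,5730
ZMB,Zambia,East,2018,6334,10,74
ZWE,Zimbabwe,East,2015,9518,10,7260
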