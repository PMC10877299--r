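drug,Z1,Z2,Z3,ReZG3,RZ2,HZ,ABC,RI,H,F,GA,SCI,IS,SDD
Baraclude,110,135,18,718,47,566,15.005,9.52,4.55,296,21.22,9.96,25.96,51.33
Acetaminophen,50,53,12,248,14,230,8.10,5.18,2.45,124,10.47,5.18,11.45,27
Glecaprevir,322,390,70,2120,128,1692,45.68,26.78,12.66,912,57.55,28.15,73.80,156.16
Daclatasvir,286,341,44,1750,114,1424,42.06,25.98,12.53,742,57.28,23.94,68.03,134
Adifovir Dipivoxil,172,194,42,1020,57,806,25.94,11.95,7.33,484,32.86,15.96,45.55,92.58
Epivir-HBV,76,88,14,440,28,370,11.45,7.202,3.466,194,15.49,7.41,17.96,36.66
Morphothiadin,166,195,22,976,64,558,25.73,15.56,7.583,418,40.23,16.23,39.41,77
Sofosbuvir,187,150,45,1134,67,697,27.86,16.89,7.935,515,35.98,17.30,40.62,96.08
Pibrentasvir,436,533,64,2780,185,2054,62.32,37.705,18.266,1068,66.15,39.94,104.35,192.16
Ritonavir,248,280,44,1366,85,1182,38.25,23.97,11.53,622,51.26,24.66,58.45,122.33
Ombitasvir,338,399,56,2048,131,1678,50.27,31.18,14.93,880,67.75,32.20,79.68,101.44
Ribavirin,88,105,16,550,35,444,13.7124,8.0409,3.816,234,17.26,8.24,76.56,43
Telbivudine,88,104,18,540,34,442,13.60,8.024,3.8,234,15.22,8.23,20.46,43.33
Tenofovir alafenamide,168,435,34,970,59,615,25.40,15.66,7.46,442,33.56,16.11,38.9,83.91
Voxilaprevir,332,399,78,2200,139,1776,46.49,27.23,12.72,962,62.65,28.42,75.50,140.08
Velpatasvir,360,439,52,2284,152,1822,51.65,31.45,15.24,944,71.18,33.23,86.25,162.66
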