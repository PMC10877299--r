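drug,BP,Density,VP,EV,FP,MR,IR,LogP,MV,MW,ST
Baraclude,-,1.8±0.1,-,-,-,67.6±0.5,1.837,-0.96,153.0±7,277.279,84.2±7
Acetaminophen,387.8±25,1.3±0.1,0.0±0.9,66.2±3.0,188.4±23.2,42.4±0.3,1.619,0.34,120.9±3,151.163,52.8±3
Glecaprevir,-,1.5±0.1,-,-,-,198.2±0.4,1.610,1.71,571.5±5,838.865,64.6±5
Daclatasvir,1071.2±65,1.3±0.1,0.0±0.3,157.4±3,601.7±34.3,200.8±0.3,1.595,5.44,591.1±3,738.875,55.4±3
Adifovir Dipivoxil,641.0±65,1.4±0.1,0.0±1.9,94.6±3.0,341.5±34.3,121.0±0.5,1.569,2.45,369.1±7,501.470,51.2±7
Epivir-HBV,475.4±55,1.7±0.1,0.0±2.7,85.2±6.0,241.3±31.5,54.1±0.5,1.755,-0.71,132.2±7,229.256,79.3±7
Morphothiadin,577.2±60,1.6±0.1,0.0±1.6,86.4±3.0,302.9±32.9,120.9±0.5,1.678,3.92,320.6±7,509.392,54.0±7
Sofosbuvir,-,1.4±0.1,-,-,-,123.5±0.4,1.573,1.62,374.6±5,529.453,58.7±5
Pibrentasvir,-,1.4±0.1,-,-,-,284.5±0.3,1.614,8.71,816.6±3,1113.18,57.6±3
Ritonavir,947.0±65,1.2±0.1,0.0±0.3,144.4±3,526.6±34.3,198.9±0.3,1.600,5.28,581.7±3,720.944,53.7±3
Ombitasvir,1065.6±65,1.2±0.1,0.0±0.3,156.5±3,598.2±34.3,248.1±0.3,1.595,6.29,730.6±3,894.109,54.3±3
Ribavirin,639.8±65,2.1±0.1,0.0±2.0,99.3±3.0,340.7±34.3,51.1±0.5,1.823,-2.26,117.1±7,244.205,106.8±7
Telbivudine,-,1.5±0.1,-,-,-,55.8±0.3,1.584,-1.11,166.8±3,242.229,62.3±3
Tenofovir alafenamide,640.4±65,1.4±0.1,0.0±1.9,94.5±3.0,341.1±34.3,121.8±0.5,1.630,2.20,342.2±7,476.466,55.1±7
Voxilaprevir,-,1.4±0.1,-,-,-,207.5±0.4,1.596,3.83,610.3±5,868.934,61.5±5
Velpatasvir,-,1.3±0.1,-,-,-,-,1.643,6.78,671.6±3,883.002,60.1±3
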