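drug,provenance
Baraclude,curated standard structure (entecavir); recomputed Z1/Z2 agree with the printed tables
Acetaminophen,curated standard structure; every recomputed index reproduces the printed tables
Glecaprevir,synthetic approximate reconstruction of the drawn macrocycle; molecular formula matches the registered drug but connectivity is unverified
Daclatasvir,curated standard structure; recomputed Z1/Z2 agree with the printed tables
Adifovir Dipivoxil,curated standard structure (adefovir dipivoxil); recomputed Z1/Z2 agree with the printed tables
Epivir-HBV,curated standard structure (lamivudine); recomputed Z1/Z2 agree with the printed tables
Morphothiadin,synthetic approximate reconstruction of the drawn dihydropyrimidine; ester and morpholine chain lengths chosen consistent with the printed index values
Sofosbuvir,curated standard structure; printed index row is internally inconsistent and differs slightly from the recomputed values
Pibrentasvir,synthetic approximate reconstruction of the drawn structure; unverified connectivity
Ritonavir,curated standard structure; recomputed Z1/Z2 agree with the printed tables
Ombitasvir,synthetic approximate reconstruction; molecular formula matches the registered drug but connectivity is unverified
Ribavirin,curated standard structure; recomputed Z1/Z2 agree with the printed tables
Telbivudine,curated standard structure; recomputed Z1/Z2 agree with the printed tables
Tenofovir alafenamide,curated standard structure; printed Z2 for this drug is a misprint (violates HZ = F + 2*Z2)
Voxilaprevir,synthetic approximate reconstruction; molecular formula matches the registered drug but connectivity is unverified
Velpatasvir,synthetic approximate reconstruction; molecular formula and Z1 match but connectivity is unverified
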