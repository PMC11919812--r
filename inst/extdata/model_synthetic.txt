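format=isopeptider-logistic-1
feature_names=rmsd,r_asa
weights=-5.6977998696035295,-2.2288835947575887
intercept=5.62891312031664
threshold=0.5
training_meta=n_pos:200;n_neg:200;C:1;standardize:FALSE;converged:TRUE;date:2026-09-28;data_hash:00682e0b;source:synthetic-gaussian-fixture
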