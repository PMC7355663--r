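compound,kd_mst_uM,kd_mst_ci68_uM,mst_mode,kd_sips_uM,se_kd_sips,bmax_nmol_mg,se_bmax,n_sips,se_n,sips_status
Terazosin,29,28,initial_fluorescence,46,16,112,13,0.64,0.018,fitted
Penicillin G,3.2,7.6,mst,NA,NA,NA,NA,NA,NA,not_studied
Chloroquine,0.8,7.7,mst,76,23,380,40,0.605,0.012,fitted
Levofloxacin,46.5,40.1,mst,157,56,72,11,0.73,0.02,fitted
Papaverine,28,23,initial_fluorescence,66,18,66,8,0.715,0.015,fitted
Propranolol,80,92,initial_fluorescence,163,100,176,60,0.89,0.05,fitted
Nadolol,200,33,initial_fluorescence,340,200,68,24,0.94,0.05,fitted
Timolol,260,128,mst,120,30,39,6,0.95,0.03,fitted
Quinidine,214,29,initial_fluorescence,NA,NA,NA,NA,NA,NA,not_studied
Atropine,912,1318,mst,NA,NA,NA,NA,NA,NA,not_studied
Methotrexate,3500,13000,initial_fluorescence,NA,NA,NA,NA,NA,NA,no_binding
Diclofenac,NA,NA,mst,NA,NA,NA,NA,NA,NA,no_binding
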