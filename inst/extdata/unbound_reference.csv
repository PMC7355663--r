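compound,class_traditional,class_mst,fu_vitro_pct,fu_vivo_pct,method
Chloroquine,extreme,extreme,0.41,0.0012,sips_mass_balance
Terazosin,extreme,high,2.9,0.012,sips_mass_balance
Levofloxacin,high,high,28,0.33,sips_mass_balance
Propranolol,high,intermediate,32,0.9,sips_mass_balance
Papaverine,high,high,15,0.13,sips_mass_balance
Nadolol,intermediate,intermediate,78,8.0,sips_mass_balance
Timolol,intermediate,intermediate,71,5.7,sips_mass_balance
Atropine,intermediate,low,59,3.9,dilution_equation
Methotrexate,low,low,98,54,dilution_equation
Quinidine,high,intermediate,16,0.55,dilution_equation
Penicillin G,high,extreme,9.2,0.29,dilution_equation
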