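country,treatment,cost_eur
CZ,antihistamines,8.30
HU,antihistamines,45
FR,gp_consultation_and_medication,120
AT,specific_immunotherapy_year1,210
DE,allergic_rhinitis_management,565
IT,allergic_rhinitis_management,890
NL,rhinitis_with_comorbid_asthma,1400
UK,asthma_treatment,3200
CH,asthma_treatment,8060
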