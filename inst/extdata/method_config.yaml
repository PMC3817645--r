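# Run configuration for the dual-wavelength HMF/LA determination.
# Flat keys mirror run_config(); omitted keys fall back to method defaults.
wavelengths: [266, 284]
analytes: [HMF, LA]
epsilon_hmf: [12.38, 22.7]
epsilon_la: [0.023, 0.014]
k_hmf: 69.3
k_la: 1.62
molar_mass_hmf: 126.11
molar_mass_la: 116.12
loq_hmf: 0.017
loq_la: 4.68
dilution: 1
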