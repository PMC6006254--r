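tissue_skin_synthetic.csv / tissue_breast_synthetic.csv

Synthetic (representative) tissue optical coefficient tables for skin and
breast: absorption (mu_a, cm^-1) and reduced scattering (mu_s', cm^-1)
per wavelength (nm). Values are assembled from typical literature ranges
for human skin and breast tissue in the red/near-infrared window; they are
not measurements. Columns: wavelength_nm, mu_a_cm1, mu_s_prime_cm1.
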