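wavelength_nm,mu_a_cm1,mu_s_prime_cm1
570,0.80,36.0
606,0.60,34.0
660,0.45,30.6
700,0.38,27.0
750,0.30,24.0
800,0.24,22.0
840,0.20,20.0
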