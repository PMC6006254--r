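wavelength_nm,mu_a_cm1,mu_s_prime_cm1
570,0.25,13.5
606,0.18,12.6
660,0.13,11.23
700,0.10,10.6
750,0.08,10.0
800,0.06,9.4
840,0.05,9.0
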