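wavelength_nm,eps_hbo,eps_hbr,dpf
785,7.354e-05,1.0791e-04,6.38
808,8.618e-05,7.437e-05,6.14
850,1.0580e-04,6.913e-05,5.86
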