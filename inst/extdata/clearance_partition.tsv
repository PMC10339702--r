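compound	total_blood_clearance	fm_cyp2c8	fm_cyp3a4	fm_cyp2d6	fe_renal
HCQ	5.8	0.37	0.17	0.19	0.27
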