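name	molecular_weight	pka1	pka2	logP	fu_plasma	default_BP	ka	fa	salt_factor	kp_scalar
HCQ	335.9	9.7	8.3	3.85	0.5	7	0.5	0.75	0.775	2.2
DHCQ	307.8	9.7	8.3	3.85	0.5	7	0.5	0.75	0.775	2.2
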