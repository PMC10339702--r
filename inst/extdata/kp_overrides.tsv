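compound	organ	kp
HCQ	adipose	800
HCQ	muscle	900
DHCQ	adipose	800
DHCQ	muscle	900
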