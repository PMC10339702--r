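compound	renal_clearance	metabolic_clearance
DHCQ	2.9	8.5
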