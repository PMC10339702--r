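organ	volume_L	flow_L_h
adipose	18.2	15.6
bone	10.5	19.5
brain	1.45	46.8
gut	1.65	58.5
heart	0.33	15.6
kidney	0.31	74.1
liver	1.8	25.5
lung	0.53	NA
muscle	29	66.3
pancreas	0.14	3.9
skin	3.3	19.5
spleen	0.19	11.7
arterial_blood	1.7	NA
venous_blood	3.4	NA
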