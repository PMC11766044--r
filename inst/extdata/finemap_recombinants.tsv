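plant	phenotype	indel2601	indel2622	indel2627	indel2633	indel2640
R1	sterile	B	H	M	M	M
R2	sterile	M	M	M	H	B
R3	sterile	H	M	M	M	H
R4	sterile	M	M	M	M	H
F1	fertile	H	H	H	M	M
F2	fertile	M	M	M	M	M
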