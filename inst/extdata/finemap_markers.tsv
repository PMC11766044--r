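marker	chrom	pos
indel2601	chr5	19600000
indel2622	chr5	19800000
indel2627	chr5	19850000
indel2633	chr5	19912000
indel2640	chr5	20100000
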