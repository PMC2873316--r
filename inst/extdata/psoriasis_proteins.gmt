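psoriasis_overabundant_proteins	proteins over-abundant >= 2-fold in lesional vs uninvolved skin	KRT17	KRT14	KRT16	SERPINB4	SERPINB3	ENO1	SOD2	LGALS7B	S100A9	S100A7
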