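role	position	residue	context_motif
dyad_his	187	H	LHS
dyad_asn	253	N	PNV
ile_bact	726	I	PIx-4
ile_plant	730	I	PIx
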