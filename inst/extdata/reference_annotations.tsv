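ref_id	motif_start	motif_residues	gate_his	gate_phe	catalytic_asp	out_partner_glu	c6_partner	segment40_start	segment40_end	domain_ranges
PfuSAHH_like	55	HxExK	298	299	128	302	348	NA	NA	substrate_binding=1-200;cofactor_binding=201-350;hinge=351-360;dimerisation=361-404
SacSAHH_like	51	HxTxE	294	295	124	298	342	NA	NA	substrate_binding=1-196;cofactor_binding=197-346;hinge=347-356;dimerisation=357-400
MmaSAHH_like	70	HxExK	312	313	143	316	362	NA	NA	substrate_binding=1-214;cofactor_binding=215-364;hinge=365-374;dimerisation=375-418
LlSAHH_like	55	HxTxQ	338	339	128	342	388	151	190	substrate_binding=1-240;cofactor_binding=241-390;hinge=391-400;dimerisation=401-469
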