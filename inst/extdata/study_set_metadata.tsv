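enzyme	organism	phylum	scaffold	motif	segment	sah_cleavage	sah_synthesis	sih_cleavage	sih_synthesis
SacSAHH	Sulfolobus acidocaldarius	Crenarchaeota	SacSAHH_like	HxTxE	absent	+++	+++	-	-
SsoSAHH	Saccharolobus solfataricus	Crenarchaeota	SacSAHH_like	HxTxE	absent	+++	+++	-	-
McSAHH	Methanocella conradii	Euryarchaeota	PfuSAHH_like	HxTxE	absent	+++	++	-	+
MeSAHH	Methanohalobium evestigatum	Euryarchaeota	LlSAHH_like	HxTxE	present	+	++	-	-
MhSAHH	Methanohalophilus halophilus	Euryarchaeota	LlSAHH_like	HxTxE	present	++	++	-	+
MiSAHH	Methanocaldococcus infernus	Euryarchaeota	PfuSAHH_like	HxExK	absent	+	+	+	++
MjSIHH	Methanocaldococcus jannaschii	Euryarchaeota	PfuSAHH_like	HxExK	absent	+	++	++	+++
MmaSAHH	Methanococcus maripaludis	Euryarchaeota	MmaSAHH_like	HxExK	absent	+	++	++	+++
MtSAHH	Methanothrix thermoacetophila	Euryarchaeota	PfuSAHH_like	HxTxE	absent	+++	++	-	+
PfuSAHH	Pyrococcus furiosus	Euryarchaeota	PfuSAHH_like	HxExK	absent	+	++	++	+++
TkSAHH	Thermococcus kodakarensis	Euryarchaeota	PfuSAHH_like	HxExK	absent	+	++	++	+++
CgSAHH	Corynebacterium glutamicum	Actinomycetota	LlSAHH_like	HxTxQ	present	+++	+++	-	-
PaSAHH	Pseudomonas aeruginosa	Pseudomonadota	LlSAHH_like	HxTxQ	deleted	+++	+++	+	++
SaSAHH	Streptomyces albus	Actinomycetota	LlSAHH_like	HxTxQ	present	+++	+++	-	+
SfSAHH	Streptomyces flocculus	Actinomycetota	LlSAHH_like	HxTxQ	present	+++	+++	-	+
TmSAHH	Thermotoga maritima	Thermotogota	PfuSAHH_like	HxExK	absent	+	++	++	+++
LlSAHH	Lupinus luteus	Plantae	LlSAHH_like	HxTxQ	present	+	+++	-	-
MmSAHH	Mus musculus	Animalia	LlSAHH_like	HxTxQ	deleted	+++	+++	+	++
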