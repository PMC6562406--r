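symbol	class	substrates	notes
HAT1	acetyltransferase	H4K5,H4K12	type B HAT, newly synthesized H4
KAT2A	acetyltransferase	H3K9,H3K14	GCN5; GNAT family, SAGA/ATAC complexes
KAT2B	acetyltransferase	H3K9,H3K14	PCAF; GNAT family, mutually exclusive with KAT2A
KAT5	acetyltransferase	H4K5,H4K8,H4K12,H4K16	TIP60; NuA4 complex
KAT6A	acetyltransferase	H3K9,H3K23	MOZ; MYST family
KAT6B	acetyltransferase	H3K14,H3K23	MORF; MYST family
KAT7	acetyltransferase	H3K14,H4K5,H4K8,H4K12	HBO1; MYST family
KAT8	acetyltransferase	H4K16	MOF; MYST family
EP300	acetyltransferase	H3K18,H3K27	p300
CREBBP	acetyltransferase	H3K18,H3K27	CBP
NCOA1	acetyltransferase	H3K9,H3K14	SRC1/KAT13A; nuclear receptor coactivator
NCOA2	acetyltransferase	H3K9,H3K14	SRC2/KAT13C; putative
NCOA3	acetyltransferase	H3K9,H3K14	SRC3/KAT13B; putative
ELP3	acetyltransferase	H3K14	elongator complex
GTF3C4	acetyltransferase	H3K14	TFIIIC90; putative
GOT2	acetyltransferase	H3K14	moonlighting aspartate aminotransferase; putative
CLOCK	acetyltransferase	H3K9,H3K14	circadian regulator with HAT activity
HDAC1	deacetylase	H3K9,H3K14,H3K18,H4K16	class I; Sin3/NuRD/CoREST
HDAC2	deacetylase	H3K9,H3K14,H3K18,H4K16	class I
HDAC3	deacetylase	H3K9,H3K14,H4K16	class I; NCoR/SMRT
HDAC4	deacetylase	H3K9,H3K14	class IIa
HDAC5	deacetylase	H3K9,H3K14	class IIa
HDAC6	deacetylase	H3K9,H4K16	class IIb, largely cytoplasmic
HDAC7	deacetylase	H3K9,H3K14	class IIa
HDAC8	deacetylase	H3K9,H3K14	class I
HDAC9	deacetylase	H3K9,H3K14	class IIa
HDAC10	deacetylase	H3K9,H3K14	class IIb
HDAC11	deacetylase	H3K9,H3K14	class IV
SIRT1	deacetylase	H3K9,H3K14,H4K16	NAD-dependent; class III
SIRT2	deacetylase	H4K16	NAD-dependent
SIRT3	deacetylase	H4K16,H3K9	NAD-dependent, also mitochondrial
SIRT4	deacetylase	H3K9	NAD-dependent; putative histone activity
SIRT5	deacetylase	H3K9	NAD-dependent; putative histone activity
SIRT6	deacetylase	H3K9,H3K56	NAD-dependent
SIRT7	deacetylase	H3K18	NAD-dependent
EZH1	methyltransferase	H3K27	PRC2 catalytic subunit
EZH2	methyltransferase	H3K27	PRC2 catalytic subunit
SUV39H1	methyltransferase	H3K9	heterochromatic H3K9me3
SUV39H2	methyltransferase	H3K9	heterochromatic H3K9me3
EHMT1	methyltransferase	H3K9	GLP; H3K9me1/me2
EHMT2	methyltransferase	H3K9	G9a; H3K9me1/me2
SETDB1	methyltransferase	H3K9	H3K9me3
SETDB2	methyltransferase	H3K9	H3K9me3
SETD1A	methyltransferase	H3K4	COMPASS
SETD1B	methyltransferase	H3K4	COMPASS
SETD2	methyltransferase	H3K36	H3K36me3
SETD3	methyltransferase	H3K36	putative histone substrate
SETD7	methyltransferase	H3K4	SET7/9; H3K4me1
SETMAR	methyltransferase	H3K36	SET-transposase fusion
KMT2A	methyltransferase	H3K4	MLL1
KMT2B	methyltransferase	H3K4	MLL2
KMT2C	methyltransferase	H3K4	MLL3
KMT2D	methyltransferase	H3K4	MLL4
KMT2E	methyltransferase	H3K4	MLL5; putative
NSD1	methyltransferase	H3K36	H3K36me1/me2
NSD2	methyltransferase	H3K36	WHSC1/MMSET
NSD3	methyltransferase	H3K36	WHSC1L1
SMYD1	methyltransferase	H3K4	muscle-enriched
SMYD2	methyltransferase	H3K36	also non-histone substrates
SMYD3	methyltransferase	H3K4	also H4K5 reported
DOT1L	methyltransferase	H3K79	non-SET-domain
PRDM2	methyltransferase	H3K9	RIZ1
PRDM9	methyltransferase	H3K4,H3K36	meiotic recombination hotspots
ASH1L	methyltransferase	H3K36	trithorax-related
KMT5A	methyltransferase	H4K20	SET8/PR-Set7; H4K20me1
KMT5B	methyltransferase	H4K20	SUV420H1; H4K20me2/me3
KMT5C	methyltransferase	H4K20	SUV420H2; H4K20me2/me3
KDM1A	demethylase	H3K4,H3K9	LSD1; FAD-dependent
KDM1B	demethylase	H3K4	LSD2
KDM2A	demethylase	H3K36	JmjC
KDM2B	demethylase	H3K36	JmjC
KDM3A	demethylase	H3K9	JMJD1A
KDM3B	demethylase	H3K9	JMJD1B
KDM4A	demethylase	H3K9,H3K36	JMJD2A
KDM4B	demethylase	H3K9,H3K36	JMJD2B
KDM4C	demethylase	H3K9,H3K36	JMJD2C
KDM4D	demethylase	H3K9	JMJD2D
KDM5A	demethylase	H3K4	JARID1A
KDM5B	demethylase	H3K4	JARID1B
KDM5C	demethylase	H3K4	JARID1C
KDM5D	demethylase	H3K4	JARID1D
KDM6A	demethylase	H3K27	UTX
KDM6B	demethylase	H3K27	JMJD3
KDM7A	demethylase	H3K9,H3K27	KIAA1718
PHF8	demethylase	H3K9,H4K20	JmjC
PHF2	demethylase	H3K9	JmjC
JMJD6	demethylase	H3R2,H4R3	arginine demethylase
KDM8	demethylase	H3K36	JMJD5
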