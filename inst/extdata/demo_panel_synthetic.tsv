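# Synthetic demonstration panel: 10 mononucleotide microsatellite loci
# across 7 MSI-relevant genes. Coordinates are INVENTED (not hg19/hg38);
# for demonstrations and tests only, never for clinical interpretation.
# Columns (BED convention, 0-based half-open): chrom start end locus_id gene repeat_unit
chr2	100000	100012	ACVR2A_1	ACVR2A	A
chr2	205000	205011	ACVR2A_2	ACVR2A	T
chr17	310000	310013	RNF43_1	RNF43	A
chr17	415000	415010	RNF43_2	RNF43	T
chr3	520000	520014	TGFBR2_1	TGFBR2	A
chr13	625000	625012	HSP110_1	HSP110	T
chr13	730000	730011	HSP110_2	HSP110	A
chr7	835000	835015	BRAF_1	BRAF	A
chr4	940000	940012	KIT_1	KIT	T
chr4	1045000	1045011	TET2_1	TET2	A
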