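gene_id	label	class	chromosome	start_bp	end_bp	snv_footprint_mbp	pooled_loci	sv_subtype_filter
AR	AR gain (gene body + enhancer)	CNA_gain	chrX	67544000	67730000	NA	chrX:66920000-66940000	NA
AR	AR SNV	SNV	chrX	67544000	67730000	0.0028	NA	NA
TP53	TP53 loss	CNA_loss	chr17	7668000	7688000	NA	NA	NA
TP53	TP53 SNV	SNV	chr17	7668000	7688000	0.0012	NA	NA
TP53	TP53 SV	SV	chr17	7668000	7688000	NA	NA	NA
PTEN	PTEN loss	CNA_loss	chr10	89622000	89731000	NA	NA	NA
PTEN	PTEN SNV	SNV	chr10	89622000	89731000	0.0012	NA	NA
PTEN_ITX	PTEN SV (translocation/deletion)	SV	chr10	89000000	90000000	NA	NA	translocation,deletion
PTEN_INV	PTEN SV (inversion)	SV	chr10	89000000	90000000	NA	NA	inversion
ZNRF3	ZNRF3 loss	CNA_loss	chr22	29000000	29100000	NA	NA	NA
MYC	MYC gain	CNA_gain	chr8	127735000	127742000	NA	NA	NA
CCND1	CCND1 gain	CNA_gain	chr11	69641000	69655000	NA	NA	NA
SPOP	SPOP SNV	SNV	chr17	49598000	49678000	0.0011	NA	NA
FOXA1_NC	FOXA1 promoter ncSNV	ncSNV	chr14	37589000	37591000	0.0020	NA	NA
ERG	ERG SV	SV	chr21	38380000	38661000	NA	NA	NA
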