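voltage_gated_ion_channels	functional	SCN1A	SCN2A	SCN8A	KCNQ2	KCNQ3	KCNT1	CACNA1A	CACNA1E	CACNA1H	HCN1
gabaa_receptors	functional	GABRA1	GABRB2	GABRB3	GABRG2	GABRD
synaptic_curated	functional	STXBP1	SYNGAP1	SHANK3	DNM1	NRXN1	NLGN2	DLG4	SYT1
brain_loF_intolerant	expression	SCN1A	STXBP1	SYNGAP1	CHD2	MECP2	CDKL5	KCNQ2	DNM1	GRIN2A	GRIN2B	SLC6A1	HNRNPU
epilepsy_monogenic	disease	SCN1A	SCN2A	KCNQ2	STXBP1	CDKL5	PCDH19	DEPDC5	SLC2A1	GABRG2	GRIN2A
developmental_genes	expression	CHD2	FOXG1	ARX	TBR1	EMX2	PAX6	SOX2	OTX2
type_ii_diabetes_kegg	control	CACNA1A	CACNA1E	INS	INSR	IRS1	PIK3CA	SLC2A4	PRKCZ	MAPK1	ABCC8
fat_digestion_kegg	control	PNLIP	CEL	MGLL	DGAT1	APOA1	APOA4	FABP1	FABP2
ca_breast_kegg	control	BRCA1	BRCA2	TP53	PTEN	ATM	CHEK2	PALB2	RAD51
not_brain_expressed	control	ALB	FGA	FGB	FGG	APOH	AHSG	TTR	SERPINA1	HP	CRP
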