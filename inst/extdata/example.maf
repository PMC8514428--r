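#version 2.4
Hugo_Symbol	Variant_Classification	Tumor_Sample_Barcode	Patient_ID	Sample_Order
TP53	Missense_Mutation	LS-P001-S1	P001	1
TP53	Nonsense_Mutation	LS-P001-S1	P001	1
KRAS	Missense_Mutation	LS-P002-S1	P002	1
EGFR	Splice_Site	LS-P002-S1	P002	1
TP53	Missense_Mutation	LS-P003-S1	P003	1
BRAF	In_Frame_Del	LS-P004-S1	P004	1
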