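transcript_id	code	fate	reason
QB1_EQC	=	removed	known_mRNA
QB1_EQL	=	annotated	
QB1_EQM	=	annotated	
QB1_J	j	novel	
QB1_O	o	novel	
QB1_X	x	novel	
QB1_I	i	novel	
QB1_U	u	novel	
QB1_U199	u	removed	length_lt_200
QB1_U200	u	novel	
QB1_UM	u	removed	exons_lt_2
QB2_EQC	=	removed	known_mRNA
QB2_EQL	=	annotated	
QB2_EQM	=	annotated	
QB2_J	j	novel	
QB2_O	o	novel	
QB2_X	x	novel	
QB2_I	i	novel	
QB2_U	u	novel	
QB2_U199	u	removed	length_lt_200
QB2_U200	u	novel	
QB2_UM	u	removed	exons_lt_2
QB3_EQC	=	removed	known_mRNA
QB3_EQL	=	annotated	
QB3_EQM	=	annotated	
QB3_J	j	novel	
QB3_O	o	novel	
QB3_X	x	novel	
QB3_I	i	novel	
QB3_U	u	novel	
QB3_U199	u	removed	length_lt_200
QB3_U200	u	novel	
QB3_UM	u	removed	exons_lt_2
QB4_EQC	=	removed	known_mRNA
QB4_EQL	=	annotated	
QB4_EQM	=	annotated	
QB4_J	j	novel	
QB4_O	o	novel	
QB4_X	x	novel	
QB4_I	i	novel	
QB4_U	u	novel	
QB4_U199	u	removed	length_lt_200
QB4_U200	u	novel	
QB4_UM	u	removed	exons_lt_2
QB5_EQC	=	removed	known_mRNA
QB5_EQL	=	annotated	
QB5_EQM	=	annotated	
QB5_J	j	novel	
QB5_O	o	novel	
QB5_X	x	novel	
QB5_I	i	novel	
QB5_U	u	novel	
QB5_U199	u	removed	length_lt_200
QB5_U200	u	novel	
QB5_UM	u	removed	exons_lt_2
QB1_ORF300	u	removed	orf_ge_300
QB1_ORF297	u	novel	
QB1_DUPA	u	novel	
QB1_DUPB	u	removed	duplicate_of:QB1_DUPA
QB1_IM	i	novel	
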