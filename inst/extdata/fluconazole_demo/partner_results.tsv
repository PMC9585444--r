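partner_id	drug	adr	estimate_type	point	ci_low	ci_high	p_value	n
SNUH-MetaNurse	fluconazole	Hypokalemia	HR	1.47			<.001	
SNUH-MetaLAB	fluconazole	Hypokalemia	OR	3.04			<.001	
KYUH-MetaLAB	fluconazole	Hypokalemia	OR	1.58			<.001	
FAERS	fluconazole	Hypokalemia	ROR	1.83			<.001	
SNUH-MetaNurse	famotidine	Hepatic function abnormal	HR	1.79			<.001	
SNUH-MetaLAB	famotidine	Hepatic function abnormal	OR	2.19			.003	
KYUH-MetaLAB	famotidine	Hepatic function abnormal	OR	1.11			.008	
FAERS	famotidine	Hepatic function abnormal	OR	3.97			<.001	
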