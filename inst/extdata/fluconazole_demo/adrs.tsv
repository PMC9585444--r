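pt_name	umls_cui	soc
Hypokalemia	C0020621	Metabolism and nutrition disorders
Hepatic function abnormal	C0086565	Hepatobiliary disorders
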