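pt_name	site_id	statement	who_art_term
Hypokalemia	SNUH	Serum potassium levels under normal	Hypokalemia
Hypokalemia	SNUH	Hypokalemia	Hypokalemia
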