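drug	adr	label	evidence
fluconazole	Hypokalemia	positive	FDA product label
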