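protein_id	type	position	ref	alt
EGFRL	sub	11	L	R
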