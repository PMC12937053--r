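>EGFRL synthetic EGFR-like fragment (miniature context around an L>R substitution)
MAAAKITDFGLAKEEEGK
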