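sequence	start	end	protease	charge	label	light_mz	heavy_mz
ITDFGRAK	1	8	lysc	2	heavy_K	454.2534	458.2605
ELREATSPK	1	9	lysc	2	heavy_K	515.78	519.7871
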