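source_id	source_type	target_id	target_type	weight
CHCHD6	gene	CHCHD3	gene	0.9
CHCHD6	gene	IMMT	gene	0.8
CHCHD6	gene	APP	gene	0.7
APP	gene	BACE1	gene	0.6
IMMT	gene	OPA1	gene	0.5
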