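source_id	source_type	target_id	target_type
alzheimer disease	disease	APP	gene
alzheimer disease	disease	PSEN1	gene
mitochondrial myopathy	disease	IMMT	gene
cardiomyopathy	disease	MAPT	gene
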