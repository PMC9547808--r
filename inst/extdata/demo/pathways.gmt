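MICOS_COMPLEX	na	CHCHD6	CHCHD3	IMMT
AMYLOID_PROCESSING	na	APP	PSEN1	BACE1
CRISTAE_ORGANIZATION	na	IMMT	CHCHD6	OPA1
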