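direction	n_probesets
down	53
up	34
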