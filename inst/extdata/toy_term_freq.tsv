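study_id	term	frequency
S1	motor	0.021
S2	reward	0.015
S2	motor	0.002
S3	default mode	0.033
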