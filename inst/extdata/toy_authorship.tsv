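study_id	position	author
S1	1	Ada Smith
S1	2	Grace Jones
S2	1	Lin Wei
S2	2	Grace Jones
S3	1	Lin Wei
S3	2	Ada Smith
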