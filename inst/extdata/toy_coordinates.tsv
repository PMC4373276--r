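study_id	x	y	z	space
S1	-32	0	24	MNI
S1	-30	2	20	MNI
S2	32	0	24	MNI
S2	30	-2	20	MNI
S3	0	-52	8	MNI
S3	2	-50	10	TAL
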