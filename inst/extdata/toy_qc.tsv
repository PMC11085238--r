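sample	m1	m2	m3	m4	m5
s1	0	NA	0	1	2
s2	0	NA	1	0	2
s3	0	0	2	0	2
s4	0	2	0	0	1
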