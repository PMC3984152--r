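Source	SC	Thalamus	RTN	GPi/SNr	STN	GPe	Str-D2	Str-D1	CCortex
SC	0	1	0	0	0	0	0	0	0
Thalamus	0	0	1	0	1	1	1	1	1
RTN	0	-1	0	0	0	0	0	0	0
GPi/SNr	-1	-1	-1	0	0	0	0	0	0
STN	0	0	0	2	0	2	0	0	2
GPe	0	0	-1/2	-1/2	-1/2	0	-1/2	-1/2	0
Str-D2	0	0	0	0	0	-1	0	0	0
Str-D1	0	0	0	-1/2	0	-1/2	0	0	0
CCortex	1/2	1/2	1/2	0	1/2	0	1/2	1/2	0
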