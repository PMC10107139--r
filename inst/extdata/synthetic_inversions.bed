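X	2000000	9500000	mon
X	8000000	16500000	mon
X	21000000	27500000	fla
2L	1500000	7500000	fla
4	4000000	17000000	mon
5	6500000	19500000	fla
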