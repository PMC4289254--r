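chr1	0	3855	open
chr1	3855	7640	closed
chr1	7640	10152	open
chr1	10152	39552	closed
chr1	39552	42031	open
chr1	42031	55298	closed
chr1	55298	70000	open
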