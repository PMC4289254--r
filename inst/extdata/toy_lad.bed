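chr1	4039	7445	LAD
chr1	12830	39290	LAD
chr1	42107	54047	LAD
chr1	2583	2776	LAD
chr1	8388	8514	LAD
chr1	40831	40955	LAD
chr1	64783	65518	LAD
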