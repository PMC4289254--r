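gene_id	sample1	sample2	sample3	sample4	sample5
gene0001	3.291	7.862	8.492	1.04	2.627
gene0002	13.218	3.005	9.654	12.863	2.047
gene0003	0.004	0.646	0.554	0.86	0.012
gene0004	0.454	0.069	0.536	0.845	0.098
gene0005	0.786	0.351	0.65	0.165	0.011
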