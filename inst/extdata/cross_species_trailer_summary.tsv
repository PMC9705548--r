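# Published per-species summary statistics of mature tRNA length and
# genomic 3'-trailer length (terminator run k = 4, trailers > 20 nt
# excluded) for seven eukaryotes; values as printed (1 decimal).
species	mature_mean	mature_sd	n_mature	trailer_mean	trailer_sd	n_trailer
H. sapiens	74	3.4	594	8.1	3.7	412
M. musculus	74	3.7	811	7.9	3.6	343
D. melanogaster	74	3.6	295	8.5	4.0	247
A. thaliana	74	3.8	642	4.6	4.3	532
S. cerevisiae	74	3.5	275	3.0	2.6	269
S. pombe	74	3.4	171	3.3	2.8	162
T. thermophila	74	3.3	686	1.5	1.5	686
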