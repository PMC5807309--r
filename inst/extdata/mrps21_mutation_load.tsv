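# Published summary: fraction of DMS-MaPseq reads carrying n mutations
# across the 11 informative A/C sites of the 33-nt MRPS21 riboSNitch region.
# The last row (n = 4) aggregates reads with 4 or more mutations.
n_mutations	fraction
0	0.713
1	0.25
2	0.03
3	0.002
4	0.005
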