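label	chrom	start	end
11q	chr11	85000000	135006516
12	chr12	0	133851895
13q	chr13	40000000	60000000
17p	chr17	0	22200000
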