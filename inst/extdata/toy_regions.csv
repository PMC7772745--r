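CHR,BP1,BP2,region
1,100000,200000,region_1
1,1000000,1100000,region_2
1,2000000,2100000,region_3
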