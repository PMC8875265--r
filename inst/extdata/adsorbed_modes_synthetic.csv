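freq_cm1,intensity
450,12
731,25
948,18
1180,30
1355,44
1530,22
1610,100
1695,260
2890,8
3080,15
3453,90
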