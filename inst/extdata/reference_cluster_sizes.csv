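cluster,n,n_pd,n_swedd
1,32,23,9
2,28,24,4
3,51,44,7
4,44,36,8
5,12,10,2
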