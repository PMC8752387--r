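domain,level,weight
1,1,0.173
1,2,0.166
1,3,0.066
1,4,0.028
2,1,0.147
2,2,0.133
2,3,0.032
2,4,0.009
3,1,0.163
3,2,0.155
3,3,0.049
3,4,0.020
4,1,0.131
4,2,0.111
4,3,0.046
4,4,0.012
5,1,0.121
5,2,0.103
5,3,0.076
5,4,0.011
6,1,0.205
6,2,0.194
6,3,0.063
6,4,0.000
7,1,0.130
7,2,0.117
7,3,0.064
7,4,0.011
intercept,NA,-0.069
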