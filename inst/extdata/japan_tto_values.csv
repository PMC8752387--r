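state,n,mean
1112121,55,0.867
1131122,55,0.809
1131221,55,0.835
1144222,55,0.603
1241432,55,0.559
1314443,55,0.367
1322113,55,0.764
2111111,55,0.885
2122111,55,0.833
2124424,55,0.401
2141111,55,0.841
2221321,55,0.845
2234134,55,0.527
2431322,55,0.633
2433111,55,0.621
2444334,55,0.485
3133342,55,0.401
3324333,55,0.424
3343433,55,0.300
3344443,55,0.101
3421121,55,0.707
3434433,55,0.304
4131341,55,0.433
4212211,55,0.636
4332234,55,0.350
4333221,55,0.547
4344433,55,0.237
4344444,55,-0.005
4434433,55,0.234
4444323,55,0.185
4444444,110,0.011
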