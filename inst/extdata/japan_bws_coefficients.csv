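parameter,domain,level,estimate,se
b1,1,NA,0.908,0.060
sd1,1,NA,0.000,0.227
b2,2,NA,0.292,0.060
sd2,2,NA,0.118,1.295
b3,3,NA,0.666,0.061
sd3,3,NA,0.741,0.152
b4,4,NA,0.400,0.060
sd4,4,NA,0.834,0.150
b5,5,NA,0.346,0.060
sd5,5,NA,0.975,0.135
b6,6,NA,2.062,0.064
sd6,6,NA,0.509,0.138
b7,7,NA,0.360,0.068
sd7,7,NA,1.114,0.124
b11,1,1,4.764,0.067
b12,1,2,4.549,0.062
b13,1,3,1.249,0.062
b21,2,1,4.532,0.066
b22,2,2,4.085,0.065
b23,2,3,0.756,0.060
b31,3,1,4.703,0.068
b32,3,2,4.433,0.066
b33,3,3,0.952,0.060
b41,4,1,3.891,0.067
b42,4,2,3.237,0.067
b43,4,3,1.118,0.059
b51,5,1,3.612,0.070
b52,5,2,3.038,0.070
b53,5,3,2.143,0.063
b61,6,1,4.683,0.071
b62,6,2,4.301,0.071
b71,7,1,3.904,0.079
b72,7,2,3.485,0.077
b73,7,3,1.757,0.067
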