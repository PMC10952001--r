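X,Y,SNPID,SubjectID
1.36584,0.40199,Z001,13
1.28488,0.38166,Z001,16
1.35823,0.38800,Z001,24
1.30018,0.38155,Z001,51
1.29644,0.39695,Z001,62
0.33218,1.20284,Z001,63
1.32567,0.40944,Z001,73
1.34497,0.40108,Z001,121
1.30231,0.38416,Z001,123
1.31518,0.40546,Z001,136
1.34153,0.40832,Z001,137
1.58476,0.41924,Z001,138
0.35001,0.35327,Z001,139
0.37357,0.34464,Z001,141
1.35760,0.40401,Z001,151
1.18718,0.35502,Z001,167
1.40429,0.40723,Z001,174
1.67185,0.42256,Z001,203
1.66754,0.42275,Z001,211
1.69116,0.42726,Z001,216
1.74076,0.44449,Z001,229
1.72609,0.42531,Z001,238
0.29392,1.11550,Z001,269
1.60226,0.42337,Z001,277
1.65182,0.40624,Z001,285
1.69974,0.42643,Z001,299
1.63786,0.42332,Z001,308
0.30004,0.46021,Z001,233-2
0.33127,0.31929,Z001,234-2
1.62075,0.43070,Z001,238-1
1.61211,0.41000,Z001,239-2
0.29504,1.40139,Z001,251
0.44045,0.40432,Z001,260
0.27281,1.41842,Z001,267
0.26008,1.22395,Z001,268
0.27529,1.14970,Z001,270
0.29831,0.32121,Z001,286
1.68704,0.43980,Z001,290
1.57209,0.43311,Z001,294
1.48042,0.41833,Z001,295
1.68928,0.42789,Z001,JM-11
1.64988,0.42502,Z001,ZZM-2
1.67375,0.42881,Z001,277
0.23985,1.54469,Z001,278
1.63963,0.43460,Z001,285
1.65306,0.44516,Z001,Z1
0.26926,0.83101,Z001,NTC
0.79678,0.36945,Z001,NTC
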