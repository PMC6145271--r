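time_hr,state,replicate,value,sd,batch
0,y1,1,0.00132561020334,0.005,p_acidilactici
0,y1,2,0.00253068531611,0.005,p_acidilactici
0,y1,3,0.00326027471346,0.005,p_acidilactici
12,y1,1,0.0227817494683,0.005,p_acidilactici
12,y1,2,0.0282108955524,0.005,p_acidilactici
12,y1,3,0.0227210117715,0.005,p_acidilactici
24,y1,1,0.0858643233543,0.005,p_acidilactici
24,y1,2,0.0881414850874,0.005,p_acidilactici
24,y1,3,0.0833694319068,0.005,p_acidilactici
36,y1,1,0.200676314035,0.005,p_acidilactici
36,y1,2,0.19738655417,0.005,p_acidilactici
36,y1,3,0.201810990691,0.005,p_acidilactici
48,y1,1,0.261106226598,0.005,p_acidilactici
48,y1,2,0.264429979037,0.005,p_acidilactici
48,y1,3,0.257368046511,0.005,p_acidilactici
60,y1,1,0.268089205859,0.005,p_acidilactici
60,y1,2,0.279646818815,0.005,p_acidilactici
60,y1,3,0.274890680314,0.005,p_acidilactici
0,y2,1,0.514396162005,0.02,p_acidilactici
0,y2,2,0.557318741368,0.02,p_acidilactici
0,y2,3,0.536832949647,0.02,p_acidilactici
12,y2,1,0.298578302007,0.02,p_acidilactici
12,y2,2,0.299213213798,0.02,p_acidilactici
12,y2,3,0.269613864541,0.02,p_acidilactici
24,y2,1,0.18585352841,0.02,p_acidilactici
24,y2,2,0.191356743039,0.02,p_acidilactici
24,y2,3,0.136919112054,0.02,p_acidilactici
36,y2,1,0.0883689856324,0.02,p_acidilactici
36,y2,2,0.0873545455228,0.02,p_acidilactici
36,y2,3,0.0959102055706,0.02,p_acidilactici
48,y2,1,0.0815273534333,0.02,p_acidilactici
48,y2,2,0.0672180690855,0.02,p_acidilactici
48,y2,3,0.0402364698717,0.02,p_acidilactici
60,y2,1,0.0339928045083,0.02,p_acidilactici
60,y2,2,0.0374413806023,0.02,p_acidilactici
60,y2,3,0.00789487448178,0.02,p_acidilactici
0,y3,1,0.130696907727,0.006,p_acidilactici
0,y3,2,0.130344455935,0.006,p_acidilactici
0,y3,3,0.128463387347,0.006,p_acidilactici
12,y3,1,0.126970965326,0.006,p_acidilactici
12,y3,2,0.131135497217,0.006,p_acidilactici
12,y3,3,0.124163649885,0.006,p_acidilactici
24,y3,1,0.125671662969,0.006,p_acidilactici
24,y3,2,0.130201147794,0.006,p_acidilactici
24,y3,3,0.127036814886,0.006,p_acidilactici
36,y3,1,0.131675939238,0.006,p_acidilactici
36,y3,2,0.13197541605,0.006,p_acidilactici
36,y3,3,0.143920033623,0.006,p_acidilactici
48,y3,1,0.131484554727,0.006,p_acidilactici
48,y3,2,0.131733316532,0.006,p_acidilactici
48,y3,3,0.120428606504,0.006,p_acidilactici
60,y3,1,0.120205111991,0.006,p_acidilactici
60,y3,2,0.131180019069,0.006,p_acidilactici
60,y3,3,0.118799730346,0.006,p_acidilactici
0,y4,1,0,0.03,p_acidilactici
0,y4,2,0,0.03,p_acidilactici
0,y4,3,0,0.03,p_acidilactici
12,y4,1,0.747597725924,0.03,p_acidilactici
12,y4,2,0.783676166405,0.03,p_acidilactici
12,y4,3,0.833031087705,0.03,p_acidilactici
24,y4,1,1.18573040252,0.03,p_acidilactici
24,y4,2,1.15870534037,0.03,p_acidilactici
24,y4,3,1.13893381415,0.03,p_acidilactici
36,y4,1,1.30511733087,0.03,p_acidilactici
36,y4,2,1.32842587935,0.03,p_acidilactici
36,y4,3,1.34569856698,0.03,p_acidilactici
48,y4,1,1.42015372526,0.03,p_acidilactici
48,y4,2,1.4532812972,0.03,p_acidilactici
48,y4,3,1.48243443611,0.03,p_acidilactici
60,y4,1,1.46202204558,0.03,p_acidilactici
60,y4,2,1.46459744676,0.03,p_acidilactici
60,y4,3,1.4434124316,0.03,p_acidilactici
0,y5,1,0,0.008,p_acidilactici
0,y5,2,0.011728881591,0.008,p_acidilactici
0,y5,3,0.00946782439933,0.008,p_acidilactici
12,y5,1,0.0213641606944,0.008,p_acidilactici
12,y5,2,0.0190780089861,0.008,p_acidilactici
12,y5,3,0.00472125357362,0.008,p_acidilactici
24,y5,1,0.0500918946181,0.008,p_acidilactici
24,y5,2,0.0315939014293,0.008,p_acidilactici
24,y5,3,0.017351889928,0.008,p_acidilactici
36,y5,1,0.0590398588586,0.008,p_acidilactici
36,y5,2,0.0559340405927,0.008,p_acidilactici
36,y5,3,0.052933781972,0.008,p_acidilactici
48,y5,1,0.0720840054914,0.008,p_acidilactici
48,y5,2,0.0743318705968,0.008,p_acidilactici
48,y5,3,0.0611331960435,0.008,p_acidilactici
60,y5,1,0.0980143572606,0.008,p_acidilactici
60,y5,2,0.0735899979621,0.008,p_acidilactici
60,y5,3,0.0947010691238,0.008,p_acidilactici
0,y6,1,2.51140693891,0.04,p_acidilactici
0,y6,2,2.47374444283,0.04,p_acidilactici
0,y6,3,2.51996329418,0.04,p_acidilactici
12,y6,1,0,0.04,p_acidilactici
12,y6,2,0,0.04,p_acidilactici
12,y6,3,0,0.04,p_acidilactici
24,y6,1,0,0.04,p_acidilactici
24,y6,2,0,0.04,p_acidilactici
24,y6,3,0,0.04,p_acidilactici
36,y6,1,0,0.04,p_acidilactici
36,y6,2,0,0.04,p_acidilactici
36,y6,3,0,0.04,p_acidilactici
48,y6,1,0,0.04,p_acidilactici
48,y6,2,0,0.04,p_acidilactici
48,y6,3,0,0.04,p_acidilactici
60,y6,1,0,0.04,p_acidilactici
60,y6,2,0,0.04,p_acidilactici
60,y6,3,0,0.04,p_acidilactici
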