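time_hr,state,replicate,value,sd,batch
0,y1,1,0.00660294536459,0.005,control
0,y1,2,0,0.005,control
0,y1,3,0.0046961905751,0.005,control
12,y1,1,0.0215300265582,0.005,control
12,y1,2,0.0186205724065,0.005,control
12,y1,3,0.00937332532289,0.005,control
24,y1,1,0.140347536496,0.005,control
24,y1,2,0.138922659167,0.005,control
24,y1,3,0.144591042689,0.005,control
36,y1,1,0.192997638473,0.005,control
36,y1,2,0.19332551986,0.005,control
36,y1,3,0.191714426989,0.005,control
48,y1,1,0.197317798592,0.005,control
48,y1,2,0.197295898966,0.005,control
48,y1,3,0.185690574358,0.005,control
60,y1,1,0.205206206919,0.005,control
60,y1,2,0.201553240152,0.005,control
60,y1,3,0.199559021114,0.005,control
0,y2,1,0.546905623392,0.02,control
0,y2,2,0.576794935553,0.02,control
0,y2,3,0.556426559718,0.02,control
12,y2,1,0.411669449734,0.02,control
12,y2,2,0.387122503677,0.02,control
12,y2,3,0.444279576496,0.02,control
24,y2,1,0.294710993629,0.02,control
24,y2,2,0.331908534157,0.02,control
24,y2,3,0.328365748009,0.02,control
36,y2,1,0.213445799793,0.02,control
36,y2,2,0.225189446283,0.02,control
36,y2,3,0.246795462778,0.02,control
48,y2,1,0.146367137575,0.02,control
48,y2,2,0.160274316437,0.02,control
48,y2,3,0.151852004429,0.02,control
60,y2,1,0.122918432502,0.02,control
60,y2,2,0.11991144157,0.02,control
60,y2,3,0.139554660304,0.02,control
0,y3,1,0.112560957104,0.006,control
0,y3,2,0.103649321625,0.006,control
0,y3,3,0.112463519862,0.006,control
12,y3,1,0.104144481816,0.006,control
12,y3,2,0.102150392157,0.006,control
12,y3,3,0.113761907946,0.006,control
24,y3,1,0.101937200538,0.006,control
24,y3,2,0.111002815867,0.006,control
24,y3,3,0.10416058001,0.006,control
36,y3,1,0.11771986018,0.006,control
36,y3,2,0.113481729906,0.006,control
36,y3,3,0.106796026862,0.006,control
48,y3,1,0.114042574016,0.006,control
48,y3,2,0.111805307318,0.006,control
48,y3,3,0.102227008685,0.006,control
60,y3,1,0.108035386793,0.006,control
60,y3,2,0.103688925899,0.006,control
60,y3,3,0.11196897315,0.006,control
0,y4,1,0,0.03,control
0,y4,2,0,0.03,control
0,y4,3,0,0.03,control
12,y4,1,0.578739771399,0.03,control
12,y4,2,0.611587118792,0.03,control
12,y4,3,0.577596848656,0.03,control
24,y4,1,1.0017068011,0.03,control
24,y4,2,1.01097081881,0.03,control
24,y4,3,0.999987263441,0.03,control
36,y4,1,1.21024993707,0.03,control
36,y4,2,1.16695424169,0.03,control
36,y4,3,1.21080430276,0.03,control
48,y4,1,1.27847139483,0.03,control
48,y4,2,1.36705150858,0.03,control
48,y4,3,1.30236969471,0.03,control
60,y4,1,1.40405467939,0.03,control
60,y4,2,1.41519327848,0.03,control
60,y4,3,1.39977146689,0.03,control
0,y5,1,0.0107761666772,0.008,control
0,y5,2,0,0.008,control
0,y5,3,0.00354718413853,0.008,control
12,y5,1,0.00916335547676,0.008,control
12,y5,2,0.0339764803075,0.008,control
12,y5,3,0.0224821429078,0.008,control
24,y5,1,0.031091681785,0.008,control
24,y5,2,0.0401199833278,0.008,control
24,y5,3,0.0245940078602,0.008,control
36,y5,1,0.0604567318699,0.008,control
36,y5,2,0.0391414318167,0.008,control
36,y5,3,0.0359309066171,0.008,control
48,y5,1,0.060680403086,0.008,control
48,y5,2,0.0679159317895,0.008,control
48,y5,3,0.0610336127078,0.008,control
60,y5,1,0.0666731882215,0.008,control
60,y5,2,0.0821620928891,0.008,control
60,y5,3,0.092071296548,0.008,control
0,y6,1,2.42165948927,0.04,control
0,y6,2,2.55894359574,0.04,control
0,y6,3,2.48100464154,0.04,control
12,y6,1,1.59198095954,0.04,control
12,y6,2,1.47975991141,0.04,control
12,y6,3,1.54230968749,0.04,control
24,y6,1,0.964233288292,0.04,control
24,y6,2,0.982975272392,0.04,control
24,y6,3,0.959495232251,0.04,control
36,y6,1,0.714206764133,0.04,control
36,y6,2,0.748080386957,0.04,control
36,y6,3,0.679675998287,0.04,control
48,y6,1,0.51319581817,0.04,control
48,y6,2,0.477841251527,0.04,control
48,y6,3,0.562140530585,0.04,control
60,y6,1,0.438856213044,0.04,control
60,y6,2,0.353811915145,0.04,control
60,y6,3,0.47562613817,0.04,control
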