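input,hidden_1,hidden_2,hidden_3,hidden_4,hidden_5,hidden_6,hidden_7,hidden_8,hidden_9,hidden_10,hidden_11
A,0.055,0.184,-0.187,0.839,0.337,0.062,0.114,0.217,0.214,0.178,0.335
GA,0.663,-0.232,0.355,0.748,0.278,0.23,-0.118,0.494,-0.062,-0.835,-0.301
C,0.021,-0.277,0.33,-0.222,-0.196,0.169,-0.083,0.242,0.163,-0.224,-0.148
CA,0.124,-0.26,0.006,0.003,-0.214,0.101,-0.221,-0.272,-0.378,-0.116,-0.49
pCA,0.018,-0.314,-0.248,-0.136,-0.025,-0.303,-0.185,-0.502,-0.353,-0.024,0.008
pCB2,-0.488,0.027,-0.009,-0.886,-0.339,-0.144,0.114,-0.1,0.103,0.399,0.351
E,-0.21,-0.042,0.113,-0.605,-0.171,-0.016,0.1,0.072,0.027,-0.014,0.266
Q3ga,0.009,0.11,-0.063,0.52,0.06,0.162,0.127,0.369,0.301,-0.013,0.189
Q3gl,-0.174,0.233,0.23,-0.133,-0.215,0.396,0.247,0.552,0.198,0.003,-0.097
P,-0.235,0.04,-0.384,-0.537,-0.234,-0.399,-0.193,-0.77,-0.482,0.223,0.258
Q3ru,-0.215,0.261,-0.144,0.243,-0.168,0.031,0.094,0.033,0.042,0.274,0.016
Q3rh,-0.231,0.351,-0.342,0.396,0.14,-0.041,0.306,0.083,0.203,0.374,0.436
Bias,-0.08,-0.12,0.022,-0.162,-0.067,0.006,-0.01,-0.038,-0.145,-0.157,0.099
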