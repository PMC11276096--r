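output,hidden_1,hidden_2,hidden_3,hidden_4,hidden_5,hidden_6,hidden_7,hidden_8,hidden_9,hidden_10,hidden_11,Bias
DPPH,-0.193,-0.669,0.025,-0.005,0.357,0.025,-0.198,0.227,0.532,0.423,-0.074,-0.118
FRAP,0.438,-0.143,0.419,0.598,-0.262,0.269,-0.126,0.371,0.01,-0.493,-0.62,0.152
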