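test,actual_obtusa,actual_japonica,estimated_obtusa,estimated_japonica
1,562,647,570,590
2,404,732,510,630
3,845,1567,375,1825
4,1383,1099,1225,1175
5,200,715,210,750
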