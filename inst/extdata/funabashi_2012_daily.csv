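date,durham_obtusa,durham_japonica,ame_obtusa,ame_japonica,cc_obtusa,cc_japonica,confident,valid_plots
2012-03-24,1.2,52.2,8.5,15.2,0.67,0.89,FALSE,435
2012-03-25,0.6,73.5,1.7,69.4,2.07,1.43,TRUE,309
2012-03-26,0.9,38.0,1.7,52.5,4.37,5.03,TRUE,1434
2012-03-27,1.4,13.4,15.2,8.5,2.77,3.65,TRUE,2081
2012-03-28,7.0,25.1,8.5,25.4,6.44,6.72,TRUE,2288
2012-03-29,28.3,21.7,11.9,11.9,3.10,3.87,TRUE,1844
2012-03-30,6.2,4.6,18.6,1.7,2.07,2.44,TRUE,1440
2012-03-31,10.5,29.6,8.5,32.2,3.39,4.21,TRUE,1877
2012-04-01,7.3,47.1,15.2,35.6,3.56,4.03,TRUE,1944
2012-04-02,37.7,4.0,1.7,25.4,1.49,1.22,FALSE,515
2012-04-03,11.1,3.9,5.1,18.6,3.97,4.71,TRUE,2019
2012-04-04,23.8,19.3,25.4,35.6,4.74,5.79,TRUE,2285
2012-04-05,10.0,9.4,8.5,11.9,2.73,3.78,TRUE,1907
2012-04-06,22.4,24.1,35.6,15.2,4.17,4.85,TRUE,1981
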