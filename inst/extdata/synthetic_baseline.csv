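rookery,SIZE,P_ST1,P_ST2,Hap01,Hap02,Hap03,Hap04,Hap05,Hap06,Hap07,Hap08
RK01,4526.29973825934,0.00463081694281003,0.268801588967831,6,7,1,0,25,1,0,0
RK02,966.979608510669,0.0232302785032844,0.106306069959674,0,37,0,0,3,0,0,0
RK03,304.233178221197,0.179067984210351,0.616039633713316,1,1,0,31,7,0,0,0
RK04,947.858772392474,0.0272599652639048,0.235882192758872,0,0,24,14,2,0,0,0
RK05,41.9270258090381,0.129720017365232,0.00663154385163444,0,0,5,6,0,29,0,0
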