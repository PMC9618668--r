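stock,Hap01,Hap02,Hap03,Hap04,Hap05,Hap06,Hap07,Hap08
ST1,2,4,7,37,9,1,0,0
ST2,3,6,3,3,10,0,0,0
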