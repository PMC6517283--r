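id,time,eGFR,PU
001,0.00,1,2
001,1.14,1,2
001,2.17,2,2
001,3.05,2,3
002,0.00,1,1
002,1.54,1,1
002,2.97,1,2
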