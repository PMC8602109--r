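system,state,rep1,rep1_sd,rep2,rep2_sd,rep3,rep3_sd,average
a2b1,apo,2.6,0.6,2.7,0.4,2.5,0.5,2.6
a2b1,holo,2.5,0.3,2.6,0.5,2.9,0.8,2.6
a2b1,holo+ATP,2.5,0.3,2.0,0.2,2.4,0.4,2.3
a2b2,apo,3.2,0.3,2.9,0.2,3.4,0.5,3.2
a2b2,holo,4.1,0.6,2.7,0.4,3.1,0.3,3.3
a2b2,holo+ATP,2.7,0.4,3.0,0.5,3.0,0.4,2.9
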