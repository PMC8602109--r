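system,state,proj1,proj2,proj3,proj4,total
a2b1,apo,41.2,12.0,8.1,4.6,66.0
a2b1,holo,38.6,12.1,7.6,4.0,62.3
a2b1,holo+ATP,30.7,12.6,7.0,5.1,55.4
a2b2,apo,30.9,12.6,8.8,4.8,57.1
a2b2,holo,33.1,12.7,8.6,5.3,59.7
a2b2,holo+ATP,29.0,13.2,7.2,5.3,54.7
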