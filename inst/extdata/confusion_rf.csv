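truth,RD-U,RD-L,RD-ML,RD-LM,RD-M,RD-MD,RD-D
RD-U,8,0,0,0,0,0,0
RD-L,0,17,0,0,0,0,0
RD-ML,0,0,17,8,0,0,0
RD-LM,0,0,0,28,0,0,0
RD-M,0,0,0,0,22,7,0
RD-MD,0,0,0,1,1,33,0
RD-D,0,0,0,0,0,0,33
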