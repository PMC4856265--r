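((((A:1.0,B:1.0):0.8,((C:0.6)#H1:0.6::0.7,D:1.2):0.6):0.7,((#H1:0.5::0.3,E:1.1):0.5,F:1.5):0.9):1.2,OUT:1.5);
((((A:1.0,(B:0.5)#H2:0.5::0.8):0.8,((C:0.6)#H1:0.6::0.7,(#H2:0.6::0.2,D:0.6):0.6):0.6):0.7,((#H1:0.5::0.3,E:1.1):0.5,F:1.5):0.9):1.2,OUT:1.5);
((((A:1.0,(B:0.5)#H2:0.5::0.8):0.8,((C:0.6)#H1:0.6::0.7,(#H2:0.6::0.2,D:0.6):0.6):0.6):0.7,((#H1:0.5::0.3,(E:0.5)#H3:0.6::0.75):0.5,(#H3:0.6::0.25,F:0.9):0.6):0.9):1.2,OUT:1.5);
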