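id,label,f1,f2,f3,f4,f5,f6,f7,f8,f9,f10,f11,f12
cpd1,active,1,1,1,1,1,0,0,0,1,1,0,0
cpd2,active,1,1,1,1,0,1,0,0,0,0,0,0
cpd3,active,1,1,1,1,1,1,0,0,0,0,1,1
cpd4,active,1,1,1,1,1,1,1,0,0,0,0,0
cpd5,active,1,1,1,0,1,1,0,0,0,0,0,0
cpd6,active,1,1,0,1,1,1,0,0,0,0,0,1
cpd7,active,1,1,1,1,1,1,0,0,0,0,1,0
cpd8,active,0,1,1,0,0,1,0,0,0,0,0,0
cpd9,active,1,1,1,1,1,1,0,1,1,1,0,0
cpd10,active,1,1,1,1,0,1,0,0,0,0,0,1
cpd11,active,1,1,0,1,1,1,0,0,0,0,0,1
cpd12,active,1,1,1,1,0,0,0,0,0,0,0,0
cpd13,active,1,0,1,1,1,1,0,0,0,0,0,0
cpd14,active,0,1,1,1,0,1,0,0,0,0,1,0
cpd15,active,1,1,0,1,1,1,0,0,0,1,0,0
cpd16,active,1,1,1,1,0,1,0,0,0,1,0,0
cpd17,active,1,1,0,0,1,1,0,0,0,1,0,1
cpd18,active,1,1,0,1,1,1,0,0,0,0,0,0
cpd19,inactive,0,0,1,0,0,1,0,1,1,1,1,1
cpd20,inactive,0,0,0,0,0,0,1,1,1,1,1,1
cpd21,inactive,0,0,1,0,0,0,1,1,1,1,1,1
cpd22,inactive,0,0,1,0,0,0,0,1,0,1,1,0
cpd23,inactive,0,0,0,0,0,0,1,0,1,1,1,1
cpd24,inactive,0,0,0,1,0,0,0,1,1,1,1,1
cpd25,inactive,0,1,1,1,0,0,1,1,1,1,1,1
cpd26,inactive,0,0,0,0,0,0,1,1,1,1,1,0
cpd27,inactive,0,1,0,0,0,1,1,1,0,1,0,0
cpd28,inactive,1,0,0,0,0,0,1,0,1,0,1,1
cpd29,inactive,0,0,0,1,0,0,1,0,1,1,1,1
cpd30,inactive,0,1,0,0,0,0,1,1,0,0,1,1
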