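patient_id,observer1,observer2,contrast
P1,positive,positive,positive
P2,positive,positive,positive
P3,positive,positive,positive
P4,positive,positive,positive
P5,positive,positive,positive
P6,positive,positive,positive
P7,positive,positive,positive
P8,positive,positive,positive
P9,positive,positive,positive
P10,positive,positive,positive
P11,positive,positive,positive
P12,positive,positive,negative
P13,positive,negative,negative
P14,positive,negative,negative
P15,negative,positive,negative
P16,negative,positive,negative
P17,negative,positive,negative
P18,negative,negative,negative
P19,negative,negative,negative
P20,negative,negative,negative
P21,negative,negative,negative
P22,negative,negative,negative
P23,negative,negative,negative
P24,negative,negative,negative
P25,negative,negative,negative
P26,negative,negative,negative
P27,negative,negative,negative
P28,negative,negative,negative
P29,negative,negative,negative
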