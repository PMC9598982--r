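group,mean_quality
C1,0.8107
C2,0.7113
C3,0.5943
C4,0.7139
C5,0.7723
C6,0.4982
C10,0.8074
C11,0.9047
C12,0.7653
C13,0.8238
C14,0.6943
C15,0.7931
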