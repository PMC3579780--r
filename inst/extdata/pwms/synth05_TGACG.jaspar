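>SYN0005.1 TGACG
A [  0  0 12  0  0  0 12  0 12  0  0 ]
C [  0  0  0 12  0 12  0  0  0 12  0 ]
G [  0 12  0  0 12  0  0 12  0  0 12 ]
T [ 12  0  0  0  0  0  0  0  0  0  0 ]
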