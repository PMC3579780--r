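>SYN0002.1 GCBOX
A [  0  0  0  0 12  0  0  0  0  0 ]
C [ 12  0 12  0  0  0 12 12  0  0 ]
G [  0 12  0 12  0 12  0  0 12  0 ]
T [  0  0  0  0  0  0  0  0  0 12 ]
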