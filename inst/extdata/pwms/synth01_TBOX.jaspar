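>SYN0001.1 TBOX
A [ 12  0  0 12  0  0  0 12 12  0 ]
C [  0  0 12  0  0  0 12  0  0  0 ]
G [  0 12  0  0 12  0  0  0  0 12 ]
T [  0  0  0  0  0 12  0  0  0  0 ]
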