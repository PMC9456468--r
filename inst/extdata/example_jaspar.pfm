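>MX0001 DEMO1
A [ 10  0  2  8 ]
C [  0 12  1  0 ]
G [  1  0  9  2 ]
T [  1  0  0  2 ]
>MX0002 DEMO2
A  0  4  4  0  8
C  8  2  0  0  0
G  0  2  4  8  0
T  0  0  0  0  0
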