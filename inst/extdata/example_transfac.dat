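AC MX0001
XX
ID DEMO1
XX
P0      A      C      G      T
01     10      0      1      1      A
02      0     12      0      0      C
03      2      1      9      0      G
04      8      0      2      2      A
XX
//
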