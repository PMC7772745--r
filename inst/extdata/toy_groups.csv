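group,id
A,G01
A,G02
A,G03
A,G04
A,G05
A,G06
A,G07
A,G08
A,G09
A,G10
B,G01
B,G02
B,G03
B,G04
B,G05
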