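>T1
MKV
010
>T2
MKV
0-1
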