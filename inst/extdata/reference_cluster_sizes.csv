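"cluster","size"
1,7
2,94
3,19
4,9
5,13
6,22
7,23
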