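code_a,code_b
1,2
2,3
3,4
4,5
3,6a
3,7a
5,8a
5,9a
6a,6b
6b,6c
7a,7b
7b,7c
8a,8b
8b,8c
9a,9b
9b,9c
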