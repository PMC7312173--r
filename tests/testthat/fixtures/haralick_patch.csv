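2,1,2,2,2,6,8,3,5,1,8,1,5,6,4,2
1,8,1,6,6,8,8,3,3,4,4,7,1,7,2,7
2,4,7,6,3,6,6,8,8,5,1,7,7,3,4,1
7,8,5,4,4,7,3,5,2,6,6,8,8,1,4,2
7,5,5,5,5,7,4,8,1,2,4,5,6,6,2,4
2,7,3,1,2,1,5,6,1,2,4,6,4,6,1,3
3,3,7,1,2,7,2,7,7,6,5,5,6,6,3,7
7,6,2,1,5,6,1,2,7,6,3,5,7,4,1,5
1,6,1,5,6,1,1,8,1,8,1,5,2,4,1,3
4,7,8,6,3,1,2,1,4,4,7,5,5,6,2,5
5,1,6,8,5,7,8,8,2,5,5,6,8,7,2,4
5,7,5,2,4,4,5,7,8,6,2,5,2,1,4,1
6,7,4,7,6,8,1,5,7,6,4,6,3,3,3,2
7,4,4,2,7,5,3,1,7,6,2,3,7,2,2,8
4,4,7,1,1,5,2,5,2,5,3,4,5,4,6,5
8,4,2,3,8,4,2,6,4,5,5,4,6,2,7,2
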