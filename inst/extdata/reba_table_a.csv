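neck,trunk,legs1,legs2,legs3,legs4
1,1,1,2,3,4
1,2,2,3,4,5
1,3,2,4,5,6
1,4,3,5,6,7
1,5,4,6,7,8
2,1,1,2,3,4
2,2,3,4,5,6
2,3,4,5,6,7
2,4,5,6,7,8
2,5,6,7,8,9
3,1,3,3,5,6
3,2,4,5,6,7
3,3,5,6,7,8
3,4,6,7,8,9
3,5,7,8,9,9
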