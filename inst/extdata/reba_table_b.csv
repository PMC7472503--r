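lower_arm,upper_arm,wrist1,wrist2,wrist3
1,1,1,2,2
1,2,1,2,3
1,3,3,4,5
1,4,4,5,5
1,5,6,7,8
1,6,7,8,8
2,1,1,2,3
2,2,2,3,4
2,3,4,5,5
2,4,5,6,7
2,5,7,8,8
2,6,8,9,9
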