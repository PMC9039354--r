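65,Female,0.7,0.1,187,16,18,6.8,3.3,0.9,1
62,Male,10.9,5.5,699,64,100,7.5,3.2,0.74,1
40,Female,0.9,0.3,293,232,245,6.8,3.1,0.8,1
46,Male,1.8,0.7,208,19,14,7.6,4.4,1.3,2
26,Female,0.9,0.2,154,16,12,7,3.5,1,2
29,Male,0.9,0.3,202,14,11,6.7,3.6,1.1,1
17,Male,0.9,0.3,202,22,19,7.4,4.1,1.2,2
55,Female,0.7,0.2,290,53,58,6.8,3.4,1,1
57,Male,0.6,0.1,210,51,59,5.9,2.7,,1
72,Female,0.7,0.1,196,20,35,5.8,2,0.5,2
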