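n,d,altruistic_bound
4,2,32
4,3,11
5,2,68
5,3,17
5,4,7
5,5,2
6,2,216
6,3,44
6,4,16
6,5,6
6,6,4
7,2,528
7,3,110
7,4,36
7,5,11
7,6,4
7,7,2
8,2,1704
8,3,289
8,4,86
8,5,29
8,6,9
8,7,4
8,8,4
9,2,4336
9,3,662
9,4,199
9,5,59
9,6,15
9,7,8
9,8,4
9,9,4
10,2,13688
10,3,1810
10,4,525
10,5,141
10,6,43
10,7,7
10,8,5
10,9,4
10,10,4
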