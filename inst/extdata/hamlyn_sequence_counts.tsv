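sequence	images
1	705
2	1003
3	1700
4	1349
5	578
6	336
7	493
8	325
9	266
10	1139
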