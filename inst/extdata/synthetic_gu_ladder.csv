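rt_min,gu
24.40,4
29.10,5
33.55,6
37.75,7
41.70,8
45.40,9
48.85,10
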