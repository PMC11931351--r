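name,gu
FA2,5.88
FA2G1,6.75
FA2G2,7.62
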