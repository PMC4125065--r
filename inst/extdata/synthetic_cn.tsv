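1	1	220956	2
1	220957	274823	3
1	274824	1000001	2
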