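1	559937	584970
1	755449	755451
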