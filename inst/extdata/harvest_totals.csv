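hybrids,parentals,seasons
62431,326586889,fall 1996 through fall 2019
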