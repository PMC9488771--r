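variant,sire_heavier_sire_longer,sire_heavier_sire_shorter,dam_heavier_sire_longer,dam_heavier_sire_shorter
all,31,2,14,12
reduced,28,2,14,5
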