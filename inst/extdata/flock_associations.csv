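pair,father_flock,mother_flock
Anas_acuta x Anas_crecca_carolinensis,0,1
Anas_platyrhynchos x Mareca_strepera,1,3
Anas_acuta x Anas_platyrhynchos,0,6
Spatula_clypeata x Spatula_discors,1,0
Mareca_americana x Spatula_clypeata,0,1
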