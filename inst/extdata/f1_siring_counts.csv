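pair,section,n_f1,asymmetry_mm,asymmetry_estimated,sire_longer,sire_shorter
Anas_acuta x Mareca_americana,large,1,129,FALSE,0,1
Anas_acuta x Anas_platyrhynchos,large,16,76,FALSE,14,2
Anas_crecca_carolinensis x Mareca_strepera,large,2,71,FALSE,2,0
Aix_sponsa x Anas_crecca_carolinensis,large,1,69,FALSE,1,0
Anas_acuta x Anas_crecca_carolinensis,large,2,64,FALSE,1,1
Anas_platyrhynchos x Mareca_strepera,large,22,58,FALSE,18,4
Aix_sponsa x Anas_platyrhynchos,large,4,56,FALSE,4,0
Anas_platyrhynchos x Mareca_americana,large,9,52,FALSE,3,6
Aix_sponsa x Aythya_americana,large,1,52,FALSE,1,0
Aythya_americana x Aythya_valisineria,large,1,39,FALSE,1,0
Mareca_americana x Spatula_clypeata,small,1,17,TRUE,1,0
Mareca_strepera x Spatula_clypeata,small,3,11,TRUE,1,2
Bucephala_clangula x Lophodytes_cucullatus,small,2,9,FALSE,2,0
Anas_platyrhynchos x Aythya_americana,small,1,4,FALSE,0,1
Mareca_americana x Mareca_penelope,small,11,1,FALSE,1,10
Spatula_clypeata x Spatula_discors,small,3,1,TRUE,3,0
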