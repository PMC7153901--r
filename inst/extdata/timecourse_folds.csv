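species,time_hr,fold_drop
lst1_sygl1_mrna,1,3
lst1_protein,2,5
lst1_protein,4,10
sygl1_protein,2,3
sygl1_protein,4,10
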