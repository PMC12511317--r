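group,subgroup,count
ibs,ibs_c,133
ibs,ibs_m,237
ibs,ibs_d,246
ibs,ibs_u,26
functional_constipation,all,173
functional_diarrhoea,all,157
non_classifiable,syndromic_overlap,130
non_classifiable,classification_excluded,73
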