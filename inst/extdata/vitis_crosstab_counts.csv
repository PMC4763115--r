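table_id,block,row_group,row_type,pred_group,count,self_consistent
3,untreated,vinifera_untreated,training,vinifera,775,TRUE
3,untreated,vinifera_untreated,training,sylvestris,46,TRUE
3,untreated,sylvestris_untreated,training,vinifera,71,TRUE
3,untreated,sylvestris_untreated,training,sylvestris,333,TRUE
3,charred_mf,vinifera_charred,training,vinifera,1055,FALSE
3,charred_mf,vinifera_charred,training,sylvestris,21,FALSE
3,charred_mf,sylvestris_charred,training,vinifera,90,FALSE
3,charred_mf,sylvestris_charred,training,sylvestris,270,FALSE
4,charred_vs_untreated_wild,charred,training,charred,348,TRUE
4,charred_vs_untreated_wild,charred,training,untreated,12,TRUE
4,charred_vs_untreated_wild,untreated,training,charred,12,TRUE
4,charred_vs_untreated_wild,untreated,training,untreated,392,TRUE
4,charred_vs_untreated_cult,charred,training,charred,968,TRUE
4,charred_vs_untreated_cult,charred,training,untreated,108,TRUE
4,charred_vs_untreated_cult,untreated,training,charred,200,TRUE
4,charred_vs_untreated_cult,untreated,training,untreated,621,TRUE
5,temp_240,vinifera_240,training,vinifera,357,TRUE
5,temp_240,vinifera_240,training,sylvestris,1,TRUE
5,temp_240,sylvestris_240,training,vinifera,27,TRUE
5,temp_240,sylvestris_240,training,sylvestris,93,TRUE
5,temp_290,vinifera_290,training,vinifera,348,TRUE
5,temp_290,vinifera_290,training,sylvestris,12,TRUE
5,temp_290,sylvestris_290,training,vinifera,27,TRUE
5,temp_290,sylvestris_290,training,sylvestris,93,TRUE
5,temp_310,vinifera_310,training,vinifera,348,TRUE
5,temp_310,vinifera_310,training,sylvestris,10,TRUE
5,temp_310,sylvestris_310,training,vinifera,19,TRUE
5,temp_310,sylvestris_310,training,sylvestris,101,TRUE
6,hearth2_unknowns,vinifera_mf,training,vinifera,1055,FALSE
6,hearth2_unknowns,vinifera_mf,training,sylvestris,21,FALSE
6,hearth2_unknowns,sylvestris_mf,training,vinifera,90,FALSE
6,hearth2_unknowns,sylvestris_mf,training,sylvestris,270,FALSE
6,hearth2_unknowns,unknown_cultivated_h2,unknown,vinifera,85,FALSE
6,hearth2_unknowns,unknown_cultivated_h2,unknown,sylvestris,20,FALSE
6,hearth2_unknowns,unknown_wild_h2,unknown,vinifera,22,FALSE
6,hearth2_unknowns,unknown_wild_h2,unknown,sylvestris,96,FALSE
7,arch_vs_mf,vinifera_mf,training,vinifera,1055,FALSE
7,arch_vs_mf,vinifera_mf,training,sylvestris,21,FALSE
7,arch_vs_mf,sylvestris_mf,training,vinifera,90,FALSE
7,arch_vs_mf,sylvestris_mf,training,sylvestris,270,FALSE
7,arch_vs_mf,archaeological,unknown,vinifera,3,FALSE
7,arch_vs_mf,archaeological,unknown,sylvestris,13,FALSE
8,arch_flu_san,FLU,training,FLU,146,FALSE
8,arch_flu_san,FLU,training,SAN,34,FALSE
8,arch_flu_san,SAN,training,FLU,33,FALSE
8,arch_flu_san,SAN,training,SAN,11,FALSE
8,arch_flu_san,archaeological,unknown,FLU,5,FALSE
8,arch_flu_san,archaeological,unknown,SAN,11,FALSE
9,hearth2_large,vinifera_h2,training,vinifera,7094,TRUE
9,hearth2_large,vinifera_h2,training,sylvestris,106,TRUE
9,hearth2_large,sylvestris_h2,training,vinifera,442,TRUE
9,hearth2_large,sylvestris_h2,training,sylvestris,3158,TRUE
9,hearth2_large,archaeological,unknown,vinifera,4,TRUE
9,hearth2_large,archaeological,unknown,sylvestris,12,TRUE
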