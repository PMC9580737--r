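image_id,sample_id,gp_cocci,gp_rods,gp_diplococci,gp_pleomorphic,gn_cocci,gn_rods_short,gn_rods_long,immune_cells,mature_ec,intermediate_ec,parabasal_ec,mucus_grade,scant_bacteria,quality
I00001,S0001,3,4,0,0,9,5,0,0,0,0,0,0,0,ok
I00002,S0001,3,11,1,0,6,12,3,0,0,0,0,1,1,ok
I00003,S0001,0,0,0,3,5,3,4,3,0,0,0,0,1,ok
I00004,S0002,8,2,0,0,26,2,0,6,0,0,0,0,0,ok
I00005,S0002,5,1,0,0,13,2,0,0,0,1,1,0,0,ok
I00006,S0002,4,0,0,0,10,23,3,0,0,1,0,3,0,ok
I00007,S0002,0,1,0,0,16,3,0,1,0,2,0,0,0,ok
I00008,S0002,6,0,0,0,1,9,0,1,0,0,1,0,1,ok
I00009,S0003,0,0,0,0,13,3,0,4,0,0,0,2,0,ok
I00010,S0003,0,5,0,0,31,18,0,0,0,0,0,1,1,duplicate
I00011,S0004,11,0,0,0,28,5,1,0,0,0,0,2,0,ok
I00012,S0004,3,0,0,0,11,1,11,0,3,0,0,3,1,too_sparse
I00013,S0004,1,7,0,0,7,1,0,5,0,1,0,1,1,ok
I00014,S0005,2,3,0,2,7,5,3,0,0,0,0,0,0,ok
I00015,S0005,3,4,0,0,10,5,2,0,1,0,0,0,0,ok
I00016,S0005,3,50,0,0,34,10,0,0,1,0,0,0,0,ok
I00017,S0006,0,8,0,0,6,18,7,0,0,1,0,0,0,ok
I00018,S0006,3,2,4,1,6,28,0,0,0,0,0,0,0,ok
I00019,S0006,3,2,0,3,16,10,1,0,0,1,0,2,0,ok
I00020,S0007,3,0,1,0,8,13,0,0,0,0,0,1,0,ok
I00021,S0007,7,22,0,0,10,12,0,0,1,0,0,0,1,ok
I00022,S0007,0,16,0,0,12,40,5,0,2,0,0,3,0,ok
I00023,S0007,13,9,0,0,21,12,2,0,5,0,0,0,0,ok
I00024,S0008,4,3,1,0,21,23,0,0,0,2,0,0,1,ok
I00025,S0008,20,1,0,0,28,12,0,0,3,0,0,0,0,ok
I00026,S0008,7,5,2,4,17,21,1,0,0,0,0,0,1,ok
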