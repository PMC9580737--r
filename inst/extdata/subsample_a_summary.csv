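category,group,mean,sd,n,printed_p
gp_cocci,inflamed,5.4,9.1,98,1.8e-2
gp_cocci,normal,8.8,9.3,72,1.8e-2
gp_rods,inflamed,3.6,7.0,98,7.2e-3
gp_rods,normal,7.6,11.0,72,7.2e-3
gp_diplococci,inflamed,0.4,1.1,99,8.3e-4
gp_diplococci,normal,1.5,2.4,70,8.3e-4
gp_pleomorphic,inflamed,0.6,2.7,99,4.3e-1
gp_pleomorphic,normal,1.0,2.4,72,4.3e-1
gn_cocci,inflamed,17.3,10.8,98,1.4e-1
gn_cocci,normal,15.0,9.1,72,1.4e-1
gn_rods_short,inflamed,8.3,8.1,97,1.6e-6
gn_rods_short,normal,16.7,12.3,72,1.6e-6
gn_rods_long,inflamed,0.5,1.4,98,2.7e-4
gn_rods_long,normal,1.9,2.9,72,2.7e-4
immune_cells,inflamed,2.0,2.8,98,5.7e-10
immune_cells,normal,0.1,0.3,72,5.7e-10
mature_ec,inflamed,0.4,1.2,98,3.2e-2
mature_ec,normal,0.8,1.2,72,3.2e-2
intermediate_ec,inflamed,0.4,0.8,98,3.1e-1
intermediate_ec,normal,0.3,0.6,72,3.1e-1
parabasal_ec,inflamed,0.2,0.5,98,4.9e-1
parabasal_ec,normal,0.1,0.6,72,4.9e-1
mucus_grade,inflamed,1.5,0.6,39,3.9e-1
mucus_grade,normal,1.8,0.9,12,3.9e-1
scant_bacteria,inflamed,1.0,0.1,50,3.2e-1
scant_bacteria,normal,1.0,0.0,25,3.2e-1
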