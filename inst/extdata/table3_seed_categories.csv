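maternal_level,cell_id,category,embryo_level,endosperm_level,count,printed_pct,printed_embryo_mode,printed_endosperm_mode,footnote,pooled
2,d2_1,2x_emb/3x_end,2,3,240,97.17,S,pseudogamous,,FALSE
2,d2_2,3x_emb/4x_end,3,4,5,2.02,S,pseudogamous,a,FALSE
2,d2_3,2x_emb/6x_end,2,6,2,0.81,S,ep,,FALSE
3,t3_1,3x_emb/8x_end,3,8,457,38.13,P,pseudogamous,,FALSE
3,t3_2,3x_emb/~8.5x-9x-~9.5x_end,3,9,289,24.74,P,pseudogamous,b,TRUE
3,t3_3,3x_emb/10x_end,3,10,136,11.64,P,pseudogamous,,FALSE
3,t3_4,3x_emb/7x_end,3,7,83,7.11,P,pseudogamous,,FALSE
3,t3_5,3x_emb/~7.5x_end,3,7.5,54,4.62,P,pseudogamous,,FALSE
3,t3_6,3x_emb/6x-~6.5x_end,3,6,4,0.34,P,aute,,TRUE
3,t3_7,3x_emb/~>10x_end,3,11,61,5.22,P,unresolved,c,TRUE
3,t3_8,~3.5x_emb/9x-12x_end,3.5,9,3,0.26,unresolved,unresolved,d,TRUE
3,t3_9,~3.5x_emb/5x_end,3.5,5,1,0.09,S,pseudogamous,reconstructed,FALSE
3,t3_10,3x_emb/~5.5x_end,3,5.5,3,NA,,,reconstructed,FALSE
3,t3_11,4x_emb/7x_end,4,7,31,2.65,B_III,pseudogamous,,FALSE
3,t3_12,4x-~4.5x_emb/~6.5x-~7.5x_end,4.5,7.5,8,NA,B_III,pseudogamous,reconstructed,TRUE
3,t3_13,5x_emb/8x_end,5,8,5,0.43,B_III,pseudogamous,,FALSE
3,t3_14,"4x,5x_emb/8x,10x_end",4,8,27,2.31,B_III,pseudogamous,poly,TRUE
3,t3_15,6x_emb/~>=14x_end,6,14,6,0.51,P,ep,,TRUE
4,q4_1,4x_emb/12x_end,4,12,56,50.91,P,pseudogamous,,FALSE
4,q4_2,"4x_emb/~11.5x,~12.5x_end",4,11.5,17,15.45,P,pseudogamous,e,TRUE
4,q4_3,4x_emb/10x-~10.5x_end,4,10,9,8.18,P,pseudogamous,f,TRUE
4,q4_4,4x_emb/~>12.5x_end,4,14,14,12.73,P,unresolved,c,TRUE
4,q4_5,4x_emb/~10.5x-11x_end,4,11,2,1.82,P,pseudogamous,g,TRUE
4,q4_6,2x_emb/8x-~9.5x_end,2,8,6,5.45,rP,pseudogamous,h,TRUE
4,q4_7,4x_emb/6x_end,4,6,4,3.64,S,pseudogamous,,FALSE
4,q4_8,6x_emb/10x_end,6,10,2,1.82,B_III,pseudogamous,,FALSE
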