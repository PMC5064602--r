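transporter,R_group,chain_length,clogP,Ka_chcl3_per_M,Ka_dmso_per_M,rate_1to2500_per_s,rate_1to1000_per_s,I_printed_per_s
7a,H,0,5.2,4.3e5,7.3e2,0.0010,0.0026,2.6
7b,Et,2,6.4,1.6e5,7.0e2,0.0012,0.0033,3.2
7c,Bu,4,7.9,1.6e5,7.2e2,0.0027,0.0043,5.5
7d,Hex,6,9.5,1.5e5,7.2e2,0.0031,0.0068,7.3
7e,Oct,8,11.0,1.7e5,7.1e2,0.0018,0.0034,4.0
7f,Dec,10,12.6,1.8e5,6.7e2,0.0015,0.0024,3.1
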