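k_act_lig	9.42353e-05
k_act_auto	0.000219481
k_deact_phos	0.000296216
k_deact_R	0.00100397
k_act_K3	0.000409694
k_deact_K3	0.000801022
k_act_K2	0.000129652
k_deact_K2	0.00126061
k_act_K1	0.000118952
k_deact_K1	0.000930506
k_act_P3K	0.000442403
k_deact_P3K	0.00101659
k_act_AKT	0.00017497
k_deact_AKT	0.00102144
k_act_TOR	0.000206863
k_deact_TOR	0.00096217
k_release_4E	0.000969611
k_bind_4E	0.00125752
k_unbind_4E	0.000130415
k_act_AR_h	0.000921974
k_act_AR_mapk	0.000131753
k_deact_AR	0.00111153
k_tx_PSA	0.000176147
k_tx_CYCD	0.000235401
k_tx_PHOS	0.00603194
k_rep_PHOS	0.000517688
k_tl_PSA	0.000112627
k_tl_CYCD	8.21608e-05
k_tl_PHOS	9.10856e-05
k_deg_mPSA	0.000166168
k_deg_mCYCD	0.000238381
k_deg_mPHOS	0.000235973
k_deg_PSA	7.39083e-05
k_deg_CYCD	0.00010118
k_deg_PHOS	7.73112e-05
ic_L	1.20348
ic_R	10.6748
ic_K3	11.5518
ic_K2	22.5996
ic_K1	19.1508
ic_PP	4.24773
ic_P3K	10.0993
ic_AKT	9.95041
ic_TOR	5.45849
ic_FEBP	6.62235
ic_EIF4E	4.97476
ic_RIB	3.43009
ic_HSPAR	11.607
ic_PHOS	20.1559
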