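# Ground-truth rate constants (per second; second order A.U.^-1 s^-1,
# zero order A.U. s^-1) and non-zero initial conditions (A.U., ic_ prefix).
k_act_lig	1e-4
k_act_auto	2e-4
k_deact_phos	3e-4
k_deact_R	1e-3
k_act_K3	5e-4
k_deact_K3	1e-3
k_act_K2	1e-4
k_deact_K2	1e-3
k_act_K1	1e-4
k_deact_K1	1e-3
k_act_P3K	5e-4
k_deact_P3K	1e-3
k_act_AKT	2e-4
k_deact_AKT	1e-3
k_act_TOR	2e-4
k_deact_TOR	1e-3
k_release_4E	7.5e-4
k_bind_4E	1e-3
k_unbind_4E	1e-4
k_act_AR_h	1e-3
k_act_AR_mapk	1.7e-4
k_deact_AR	1e-3
k_tx_PSA	2e-4
k_tx_CYCD	2e-4
k_tx_PHOS	7e-3
k_rep_PHOS	5e-4
k_tl_PSA	1e-4
k_tl_CYCD	1e-4
k_tl_PHOS	7e-5
k_deg_mPSA	2e-4
k_deg_mCYCD	2e-4
k_deg_mPHOS	2e-4
k_deg_PSA	1e-4
k_deg_CYCD	1e-4
k_deg_PHOS	1e-4
ic_L	1
ic_R	10
ic_K3	10
ic_K2	20
ic_K1	20
ic_PP	5
ic_P3K	10
ic_AKT	10
ic_TOR	5
ic_FEBP	8
ic_EIF4E	5
ic_RIB	3
ic_HSPAR	10
ic_PHOS	20
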