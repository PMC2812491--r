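# Reduced synthetic signaling network (toy bundle).
# Growth-factor receptor with auto-activation and phosphatase feedback,
# three-tier kinase cascade, PI3K/Akt/TOR translation-initiation branch,
# hormone receptor with chaperone sequestration and dual (hormone and
# cascade-mediated) activation, and expression of a secreted marker, a
# proliferation marker and the feedback phosphatase itself.
# Columns are tab-separated: id, compartment, initial_value (A.U.), synthesized.
[SPECIES]
L	extracellular	1	0
R	membrane	10	0
Ra	membrane	0	0
K3	cytosol	10	0
K3a	cytosol	0	0
K2	cytosol	20	0
K2a	cytosol	0	0
K1	cytosol	20	0
K1a	cytosol	0	0
PP	cytosol	5	0
P3K	cytosol	10	0
P3Ka	cytosol	0	0
AKT	cytosol	10	0
AKTa	cytosol	0	0
TOR	cytosol	5	0
TORa	cytosol	0	0
FEBP	cytosol	8	0
EIF4E	cytosol	5	0
CPLX	cytosol	0	0
RIB	cytosol	3	0
H	extracellular	0	0
HSPAR	cytosol	10	0
ARa	cytosol	0	0
mPSA	cytosol	0	1
PSA	cytosol	0	1
mCYCD	cytosol	0	1
CYCD	cytosol	0	1
mPHOS	cytosol	0	1
PHOS	cytosol	20	1
# id, equation, rate constant id(s); "<->" expands to two irreversible steps.
[REACTIONS]
r01	L + R -> L + Ra	k_act_lig
r02	R + Ra -> 2*Ra	k_act_auto
r03	Ra + PHOS -> R + PHOS	k_deact_phos
r04	Ra -> R	k_deact_R
r05	K3 + Ra -> K3a + Ra	k_act_K3
r06	K3a -> K3	k_deact_K3
r07	K2 + K3a -> K2a + K3a	k_act_K2
r08	K2a -> K2	k_deact_K2
r09	K1 + K2a -> K1a + K2a	k_act_K1
r10	K1a + PP -> K1 + PP	k_deact_K1
r11	P3K + Ra -> P3Ka + Ra	k_act_P3K
r12	P3Ka -> P3K	k_deact_P3K
r13	AKT + P3Ka -> AKTa + P3Ka	k_act_AKT
r14	AKTa -> AKT	k_deact_AKT
r15	TOR + AKTa -> TORa + AKTa	k_act_TOR
r16	TORa -> TOR	k_deact_TOR
r17	CPLX + TORa -> FEBP + EIF4E + TORa	k_release_4E
r18	FEBP + EIF4E <-> CPLX	k_bind_4E, k_unbind_4E
r19	HSPAR + H -> ARa + H	k_act_AR_h
r20	HSPAR + K1a -> ARa + K1a	k_act_AR_mapk
r21	ARa -> HSPAR	k_deact_AR
r22	ARa -> ARa + mPSA	k_tx_PSA
r23	K1a -> K1a + mCYCD	k_tx_CYCD
r24	0 -> mPHOS	k_tx_PHOS
r25	ARa + mPHOS -> ARa	k_rep_PHOS
r26	mPSA + EIF4E + RIB -> mPSA + EIF4E + RIB + PSA	k_tl_PSA
r27	mCYCD + EIF4E + RIB -> mCYCD + EIF4E + RIB + CYCD	k_tl_CYCD
r28	mPHOS + EIF4E + RIB -> mPHOS + EIF4E + RIB + PHOS	k_tl_PHOS
r29	mPSA -> 0	k_deg_mPSA
r30	mCYCD -> 0	k_deg_mCYCD
r31	mPHOS -> 0	k_deg_mPHOS
r32	PSA -> 0	k_deg_PSA
r33	CYCD -> 0	k_deg_CYCD
r34	PHOS -> 0	k_deg_PHOS
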