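clone,parameter,factor
MID,k_tx_PHOS,0.5
AI,k_tx_PHOS,0.01
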