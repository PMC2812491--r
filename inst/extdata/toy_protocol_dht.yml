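# Hormone stimulation protocol: 10 A.U. (nM-equivalent) of hormone added
# at 1 h on top of the basal level; output until 72 h after addition.
t_end_hr: 73
events:
  - time_hr: 1
    kind: add_species
    target: H
    value: 10
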