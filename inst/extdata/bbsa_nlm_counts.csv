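label,concentration_mol_dm3,n_total,n_aggregate,printed_pct,printed_pm
BBSA,1e-07,100,18,18.3,6.9
BBSA,1e-09,100,67,67.4,13.4
BBSA,1e-11,100,27,26.7,14.0
BBSA,1e-13,100,10,9.9,6.3
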