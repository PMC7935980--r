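label,concentration_mol_dm3,n_total,n_aggregate,printed_pct,printed_pm
dsDNA,1e-07,100,52,52.0,13.4
dsDNA,1e-09,100,53,53.4,18.4
dsDNA,1e-11,100,17,17.0,9.2
dsDNA,1e-13,100,23,23.4,9.3
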