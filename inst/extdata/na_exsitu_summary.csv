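rank,n_taxa,n_seed,n_living,pct_any
R1,1490,470,559,49
R2,2025,454,670,41
R3,3352,668,1146,42
R4,5582,1506,2549,52
R5,6317,3207,4357,74
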