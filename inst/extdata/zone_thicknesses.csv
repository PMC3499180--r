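delta_sigma_n,reserve_um,proliferative_um,hypertrophic_um
0.1,13.9,288,175
0.0,12.3,264,162
-0.1,11.9,269,129
-0.2,10.9,242,123
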