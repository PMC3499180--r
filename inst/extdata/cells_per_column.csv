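delta_sigma_n,proliferative,hypertrophic
0.1,23,7
0.0,22,6
-0.1,22,5
-0.2,18,5
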