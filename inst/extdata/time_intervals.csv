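delta_sigma_n,g_stokes_um_day,h_max_um,delta_t_days
0.1,228.7,36.22,0.158
0.0,217.0,35.00,0.161
-0.1,183.4,35.94,0.196
-0.2,163.8,34.30,0.209
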