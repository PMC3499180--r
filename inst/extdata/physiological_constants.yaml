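# Physiological (unloaded) reference values for the rat proximal tibia.
h_max_f_um: 35        # maximum hypertrophic chondrocyte height, physiological
columns: 20           # chondrocyte columns across the modelled section
column_spacing_um: 40 # lateral separation between columns
domain_side_um: 800   # side of the square simulation domain
duration_days: 23     # default simulated growth period
sigma_n_f_mpa: 0      # physiological axial stress baseline (loads are stated
                      # as differences from it, tension positive)
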