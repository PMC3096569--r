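# small power-study configuration (desk-scale demonstration)
p1 = 0.5
q1 = 0.5
dh = 0
n = 1000
reps = 500
dprime_grid = 0,0.05,0.1
alphas = 0.05,0.01
seed = 11
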