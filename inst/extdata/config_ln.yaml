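# Default pipeline configuration: linked-nucleosome preset at a desk-scale
# sampling budget. Stages: synthetic umbrella campaign -> WHAM -> fits.
preset: LN
outdir: results/pipeline_ln
seed: 1
n_steps: 100000
save_stride: 20
bin_width: 0.5
n_boot: 0
temperature: 303.15
stages: [simulate, wham, fit]
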