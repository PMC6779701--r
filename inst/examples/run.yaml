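# example SWISH run configuration (see inst/scripts/swish.R)
sequence: MATLEKLMKAFESLKSFQQ
mods: [pThr3]
ladder: {min: 0.85, max: 1.10, step: 0.05}
sweeps: 2000
swap_interval: 10
temperature: 300
seed: 1
record_every: 2
equilibration: 0.25
output_dir: swish_out
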