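model: lt-weibull
true: 0.2,0.5,0.8,1.2
sample_sizes: 50,100
n_reps: 25
level: 0.95
seed: 1
n_starts: 6
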