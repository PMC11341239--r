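"strength"
0.55
0.93
1.25
1.36
1.49
1.52
1.58
1.61
1.64
1.68
1.73
1.81
2
0.74
1.04
1.27
1.39
1.49
1.53
1.59
1.61
1.66
1.68
1.76
1.82
2.01
0.77
1.11
1.28
1.42
1.5
1.54
1.6
1.62
1.66
1.69
1.76
1.84
2.24
0.81
1.13
1.29
1.48
1.5
1.55
1.61
1.62
1.66
1.7
1.77
1.84
0.84
1.24
1.3
1.48
1.51
1.55
1.61
1.63
1.67
1.7
1.78
1.89
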