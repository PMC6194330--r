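# painf hidden Markov machine
# golden-mean-family process, 7-state presentation, Markov order 4
# synthetic construction: ones separated by >= 4 zeros; S0-S3 count the
# forced zeros after a one, F1-F3 cycle during the free phase and are
# observationally equivalent
# states: S0 S1 S2 S3 F1 F2 F3
# n_observables: 2
# edge format: from to probability symbol
S0	S1	1	0
S1	S2	1	0
S2	S3	1	0
S3	F1	1	0
F1	S0	0.5	1
F1	F2	0.5	0
F2	S0	0.5	1
F2	F3	0.5	0
F3	S0	0.5	1
F3	F1	0.5	0
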