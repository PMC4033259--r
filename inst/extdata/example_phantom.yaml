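# Example phantom spec: one subject, one session holding a structural
# MPRAGE-like scan, a 4D time series, and a 7-volume DWI.
kind: structural
dim: [32, 32, 32]
n_subjects: 1
n_sessions: 1
scan_kinds: [structural, timeseries, diffusion]
phi_fields: all
seed: 42
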