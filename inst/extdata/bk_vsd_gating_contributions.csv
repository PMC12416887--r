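# Per-residue contributions to the gating charge per VSD (e) for the human
# BK Core-MT channel, with block-averaging errors, and the stated per-VSD
# total of ~0.45 e. Used as the published reference input for the
# gating-charge aggregation examples.
residue,helix,contribution_e,error_e
D153,S2,0.08,0.04
R167,S2,0.002,0.03
D186,S3,-0.01,0.03
R207,S4,0.04,0.01
R210,S4,0.25,0.02
R213,S4,0.19,0.01
E219,S4,-0.09,0.02
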