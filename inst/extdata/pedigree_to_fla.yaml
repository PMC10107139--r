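# Backcrosses towards D. flavomontana: 3 F1 mothers, 22 BC1 females,
# 82 pooled BC2 females. Per-mother contributions split evenly (replace
# with realised counts when known).
direction: to_fla
bc1_per_f1: [8, 7, 7]
bc2_per_bc1: [4, 4, 4, 4, 4, 4, 4, 4, 4, 4, 4, 4, 4, 4, 4, 4, 3, 3, 3, 3, 3, 3]
pool_size: 82
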