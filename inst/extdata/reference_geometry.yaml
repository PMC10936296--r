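p0:
- 0.0
- 0.0
p1:
- 0.38
- 0.08
p2:
- 0.0
- 0.20000000000000001
p3:
- -0.14999999999999999
- 0.05
p4:
- -0.45000000000000001
- 0.02
stiffness_N_per_m: 700.0
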