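C1:
- -0.25
- 0.05
C2:
- -0.17999999999999999
- 0.03
C3:
- -0.20999999999999999
- 0.04
C4:
- 0.05
- 0.34000000000000002
C5:
- -0.20000000000000001
- 0.03
C6:
- -0.20000000000000001
- 0.02
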