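C1:
- 0.0
- 0.08
C2:
- 0.0
- 0.16
C3:
- 0.03999999999999999
- 0.06928203230275509
C4:
- 0.07999999999999999
- 0.13856406460551018
C5:
- -0.03999999999999999
- 0.06928203230275509
C6:
- -0.07999999999999999
- 0.13856406460551018
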