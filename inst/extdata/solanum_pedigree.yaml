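# Five-cohort Solanum line cross design (sire x dam notation).
# The F1 is needed to derive the other cohorts but was not phenotyped.
founders:
  - P1
  - P2
crosses:
  F1: P1 x P2
  F2: F1 x F1
  BC1: P1 x F1
  rBC2: F1 x P2
measured:
  - P1
  - P2
  - F2
  - BC1
  - rBC2
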