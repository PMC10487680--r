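qPCR SNP genotyping thermal program
  1. 95 degC  10 min   (initial denaturation)
  2. 95 degC  10 s  \
  3. 60 degC  10 s   | 45 cycles
  4. 72 degC  20 s  /
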