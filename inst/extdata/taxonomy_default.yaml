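# Default TE classification tree. Internal nodes with >= 2 children are the
# nine classifier sites: TE, ClassI, ClassII, nonLTR, LTR, ERV, LINE, SINE, TIR.
nodes:
  TE: [ClassI, ClassII]
  ClassI: [LTR, nonLTR]
  ClassII: [TIR, Helitron, Maverick]
  nonLTR: [LINE, SINE]
  LTR: [Copia, Gypsy, Bel-Pao, ERV]
  ERV: [ERV1, ERV2, ERV3]
  LINE: [L1, CR1, RTE, Rex1, Jockey, I]
  SINE: [SINE1/7SL, SINE2/tRNA, SINE3/5S, ID]
  TIR: [hAT, TcMar, MULE, PIF, CACTA, Merlin, P]
aliases:
  MITE: TIR
  Mariner: TcMar
  Tc1-Mariner: TcMar
  MuDR: MULE
  EnSpm: CACTA
  "PIF-Harbinger": PIF
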