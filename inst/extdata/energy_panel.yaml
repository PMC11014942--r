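# Energy-conservation / carbon-acquisition marker panel for genome-level
# screening. Covers aerobic respiration, trace-gas oxidation (CO via coxL,
# H2 via uptake [NiFe]-hydrogenases) and the CBB and 3-hydroxypropionate
# carbon-fixation pathways. User-extensible: add processes or genes freely.
processes:
  aerobic_respiration: [coxA, ccoN, cydA]
  CO_oxidation: [coxL]
  H2_oxidation: [hhyL, hybB]
  CBB_cycle: [rbcL, cbbL]
  3HP_cycle: [mcr, pccB]
aliases:
  cbblr: cbbL
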