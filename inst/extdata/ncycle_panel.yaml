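# Nitrogen-cycle marker panel: process -> qPCR/metagenome marker genes.
# nirS/nirK also occur in nitrifiers; this default credits them to
# denitrification only (see the dual_nir option of ncycle_panel()).
processes:
  N2_fixation: [nifH]
  nitrification: [amoA, hao, nxrB]
  denitrification: [napA, narG, nirS, nirK, norB, nosZ]
  DNRA: [nrfA]
  ANR: [nasA, nirA]
  anammox: [hzo, hzs]
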