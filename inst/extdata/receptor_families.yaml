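# Receptor-to-neurotransmitter-family map, version 1.
# ASCII-safe receptor labels as used across the package.
version: 1
families:
  glutamate: [AMPA, NMDA, kainate]
  GABA: [GABAA, GABAB, BZ]
  acetylcholine: [M1, M2, M3, alpha4beta2]
  noradrenaline: [alpha1, alpha2]
  serotonin: [5HT1A, 5HT2]
  dopamine: [D1]
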