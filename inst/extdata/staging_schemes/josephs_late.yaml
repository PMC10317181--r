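# Six-stage medial-temporal TDP-43 scheme.
# PROVISIONAL region memberships: edit to match the published definition
# before applying to real data.
name: Josephs TDP-43 (provisional)
stages:
  I: [amygdala]
  II: [entorhinal_cortex, dentate_gyrus]
  III: [ca_subiculum]
  IV: [sup_mid_temporal]
  V: [middle_frontal, anterior_cingulate]
  VI: [caudate_putamen, substantia_nigra, midbrain]
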