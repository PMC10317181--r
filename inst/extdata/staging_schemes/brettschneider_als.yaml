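# Four-stage ALS scheme (caudorostral spread from motor system).
# PROVISIONAL region memberships: edit to match the published definition
# before applying to real data.
name: Brettschneider ALS (provisional)
stages:
  I: [motor_cortex, spinal_cord, medulla]
  II: [midbrain, upper_pons, locus_coeruleus]
  III: [middle_frontal, caudate_putamen]
  IV: [ca_subiculum, entorhinal_cortex]
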