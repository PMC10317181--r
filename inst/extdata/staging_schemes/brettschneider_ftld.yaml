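# Four-stage FTLD/bvFTD scheme (frontotemporal outward spread).
# PROVISIONAL region memberships: edit to match the published definition
# before applying to real data.
name: Brettschneider FTLD-bvFTD (provisional)
stages:
  I: [orbitofrontal_cortex, amygdala]
  II: [middle_frontal, anterior_cingulate, sup_mid_temporal, caudate_putamen]
  III: [motor_cortex, spinal_cord]
  IV: [occipital_cortex]
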