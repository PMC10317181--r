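# Five-stage scheme (amygdala through limbic to neocortical spread).
# PROVISIONAL region memberships: edit to match the published definition
# before applying to real data.
name: Rush LATE-NC (provisional)
stages:
  I: [amygdala]
  II: [entorhinal_cortex]
  III: [ca_subiculum, dentate_gyrus]
  IV: [anterior_cingulate, sup_mid_temporal]
  V: [middle_frontal, angular_gyrus, occipital_cortex]
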