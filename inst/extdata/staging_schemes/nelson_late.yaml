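# Three-stage LATE-NC scheme (amygdala -> hippocampus -> neocortex).
# PROVISIONAL region memberships: edit to match the published definition
# before applying to real data.
name: Nelson LATE-NC (provisional)
stages:
  I: [amygdala]
  II: [ca_subiculum, dentate_gyrus, entorhinal_cortex]
  III: [middle_frontal]
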