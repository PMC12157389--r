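# Example cohort design for `clutchcorrect simulate`
genotypes: [control, mutA, mutB]
control: control
clutches: [c1, c2]
ages: [3dpf, 5dpf]
assignment:
  c1: [control, mutA]
  c2: [control, mutB]
n_per_group: 10
image_shape: [64, 128]
seed: 7
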