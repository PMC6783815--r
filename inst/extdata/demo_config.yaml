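# Demo: two synthetic populations (flat wild-type-like vs twisted/undulating
# mutant-like thallus sheets), full scene simulation + extraction, descriptor
# measurement and LDA classification.
seed: 7
spacing: 1.0
out_dir: demo_out
jitter: 0.1
scenes: true
noise_sd: 5
groups:
  - label: WT
    n: 18
    shape: slab
    size: {length: 40, width: 16, thickness: 4}
  - label: mutant
    n: 18
    shape: twisted_slab
    size: {length: 40, width: 16, thickness: 4}
    twist: 180
    undulation_amplitude: 2
    undulation_period: 15
extraction:
  high_threshold: auto
  plant_threshold: auto
  min_component_size: 27
  connectivity: 26
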