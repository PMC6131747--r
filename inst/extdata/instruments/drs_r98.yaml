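# Delirium Rating Scale-Revised-98: 13 severity items, each rated
# 0 (not present) / 1 (mild) / 2 (moderate) / 3 (severe).
# `shared` marks the coarse symptom domain common to all three instruments;
# `domain` is the fine-grained label used for pairwise anchor matching.
# Sleep disturbance dichotomizes at moderate-or-worse (cut 2); all other
# items at any-symptom (cut 1).
name: DRS-R-98
items:
  - id: sleep_wake_disturbance
    domain: sleep_wake
    shared: sleep_wake
    categories: 4
    cut: 2
  - id: perceptual_disturbance
    domain: perceptual_disturbance
    shared: perceptual_disturbance
    categories: 4
  - id: delusions
    domain: delusions
    categories: 4
  - id: lability_of_affect
    domain: lability_of_affect
    categories: 4
  - id: language
    domain: language
    categories: 4
  - id: thought_process
    domain: disorganized_thinking
    shared: disorganized_thinking
    categories: 4
  - id: motor_agitation
    domain: psychomotor_agitation
    shared: psychomotor
    categories: 4
  - id: motor_retardation
    domain: psychomotor_retardation
    shared: psychomotor
    categories: 4
  - id: orientation
    domain: orientation
    shared: orientation
    categories: 4
  - id: attention
    domain: attention
    shared: attention
    categories: 4
  - id: short_term_memory
    domain: memory
    shared: memory
    categories: 4
  - id: long_term_memory
    domain: long_term_memory
    categories: 4
  - id: visuospatial
    domain: visuospatial
    categories: 4
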