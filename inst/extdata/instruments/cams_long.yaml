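# CAM-S long form: 9 CAM features rated 0 (absent) / 1 (mild) / 2 (marked)
# plus acute onset or fluctuation rated 0/1.  Sum score range 0-19.
name: CAM-S-LF
items:
  - id: acute_onset_fluctuation
    domain: acute_onset
    categories: 2
  - id: inattention
    domain: attention
    shared: attention
    categories: 3
  - id: disorganized_thinking
    domain: disorganized_thinking
    shared: disorganized_thinking
    categories: 3
  - id: altered_consciousness
    domain: consciousness
    categories: 3
  - id: disorientation
    domain: orientation
    shared: orientation
    categories: 3
  - id: memory_impairment
    domain: memory
    shared: memory
    categories: 3
  - id: perceptual_disturbance
    domain: perceptual_disturbance
    shared: perceptual_disturbance
    categories: 3
  - id: psychomotor_agitation
    domain: psychomotor_agitation
    shared: psychomotor
    categories: 3
  - id: psychomotor_retardation
    domain: psychomotor_retardation
    shared: psychomotor
    categories: 3
  - id: sleep_wake_disturbance
    domain: sleep_wake
    shared: sleep_wake
    categories: 3
    cut: 2
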