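# Memorial Delirium Assessment Scale: 10 items rated 0-3.
# The psychomotor item rates agitation/retardation jointly ("activity"),
# so it belongs to the shared psychomotor domain but is not a pairwise
# anchor against the DRS-R-98 (which rates agitation and retardation
# separately).
name: MDAS
items:
  - id: consciousness
    domain: consciousness
    categories: 4
  - id: disorientation
    domain: orientation
    shared: orientation
    categories: 4
  - id: short_term_memory
    domain: memory
    shared: memory
    categories: 4
  - id: digit_span
    domain: digit_span
    categories: 4
  - id: attention
    domain: attention
    shared: attention
    categories: 4
  - id: disorganized_thinking
    domain: disorganized_thinking
    shared: disorganized_thinking
    categories: 4
  - id: perceptual_disturbance
    domain: perceptual_disturbance
    shared: perceptual_disturbance
    categories: 4
  - id: delusions
    domain: delusions
    categories: 4
  - id: psychomotor_activity
    domain: psychomotor_activity
    shared: psychomotor
    categories: 4
  - id: sleep_wake_disturbance
    domain: sleep_wake
    shared: sleep_wake
    categories: 4
    cut: 2
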