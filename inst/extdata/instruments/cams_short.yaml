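# CAM-S short form: the four diagnostic-algorithm features of the CAM.
# Sum score range 0-7.  Scored from the long-form calibration (the short
# form is a reduced score, not a separately calibrated instrument); item
# ids match the long form so parameters can be carried over.
name: CAM-S-SF
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
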