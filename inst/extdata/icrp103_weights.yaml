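# ICRP publication 103 tissue weighting scheme.
# Explicit weights sum to 0.88; the collective remainder weight 0.12 is
# applied to the arithmetic mean equivalent dose over 13 remainder organs
# (fixed divisor, unmeasured remainder organs contribute zero).
explicit_weights:
  gonads: 0.08
  bone_marrow: 0.12
  colon: 0.12
  lung: 0.12
  stomach: 0.12
  breast: 0.12
  bladder: 0.04
  esophagus: 0.04
  liver: 0.04
  thyroid: 0.04
  bone_surface: 0.01
  brain: 0.01
  salivary_glands: 0.01
  skin: 0.01
remainder_organs:
  - adrenals
  - extrathoracic_region
  - gallbladder
  - heart
  - intestine
  - kidney
  - lymphatic_nodes
  - muscle
  - oral_mucosa
  - pancreas
  - prostate_uterus
  - spleen
  - thymus
remainder_weight: 0.12
remainder_divisor: 13
radiation_weight: 1.0
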