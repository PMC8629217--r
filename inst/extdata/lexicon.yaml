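# Toy rule lexicon for the 14 standard chest X-ray finding categories.
# A category is positive when a mention phrase occurs with no negation cue
# in the `window` tokens immediately before it.
window: 3
cues: ["no", "not", "without", "free", "absent"]
phrases:
  no_finding:
    - acute cardiopulmonary abnormality
    - acute cardiopulmonary process
  enlarged_cardiomediastinum:
    - cardiomediastinum
    - widened mediastinum
  cardiomegaly:
    - cardiomegaly
    - enlarged heart
  lung_opacity:
    - opacity
    - opacities
  lung_lesion:
    - nodule
    - lesion
    - pulmonary mass
  edema:
    - edema
  consolidation:
    - consolidation
  pneumonia:
    - pneumonia
    - infectious process
  atelectasis:
    - atelectasis
  pneumothorax:
    - pneumothorax
  pleural_effusion:
    - pleural effusion
    - effusion
    - effusions
  pleural_other:
    - pleural thickening
    - fibrothorax
  fracture:
    - fracture
    - fractures
  support_devices:
    - tube
    - catheter
    - pacemaker
    - sternotomy wires
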