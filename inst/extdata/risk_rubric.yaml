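items:
  vsgp: 40.0
  gelastic_cataplexy: 20.0
  splenomegaly: 20.0
  neonatal_jaundice: 10.0
  cognitive_impairment: 10.0
  ataxia: 10.0
  dysarthria: 10.0
  swallowing_difficulties: 10.0
  dystonia: 10.0
  psychosis: 15.0
  clumsiness: 5.0
  impaired_fine_motor: 5.0
  school_problems: 5.0
  behavioral_problems: 5.0
threshold_followup: 40.0
threshold_likely: 70.0
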