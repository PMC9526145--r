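# Default analysis configuration: the three-approach cause taxonomy,
# musculoskeletal-pain reallocation fraction with sensitivity bounds, and
# the pooled mortality relative risk applied to both cause-of-death strata.
causes:
  mental_core:
    - Schizophrenia
    - Depressive disorders
    - Bipolar disorder
    - Anxiety disorders
    - Eating disorders
    - Autism spectrum disorders
    - Attention-deficit/hyperactivity disorder
    - Conduct disorder
    - Idiopathic developmental intellectual disability
    - Other mental disorders
  substance:
    - Alcohol use disorders
    - Drug use disorders
  neurological:
    - Alzheimer's disease and other dementias
    - Parkinson's disease
    - Idiopathic epilepsy
    - Multiple sclerosis
    - Motor neuron disease
    - Headache disorders
    - Other neurological disorders
  musculoskeletal_pain:
    - Low back pain
    - Neck pain
    - Other musculoskeletal disorders
  self_harm: Self-harm
  ncd_root: Non-communicable diseases
  injuries_root: Injuries
  all_cause: All causes
  prevalence_cause: Mental disorders
msk_fraction: 0.333333333333333
msk_fraction_bounds: [0.166666666666667, 0.5]
rr:
  all_cause: {point: 2.2, lower: 2.1, upper: 2.3}
  provenance: pooled all-cause mortality RR, people with vs without mental disorders
include_substance:
  original: false
  reallocation: true
  composite: true
composite_self_harm_yld: false
year: 2019
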