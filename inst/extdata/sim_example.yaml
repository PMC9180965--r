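# Example simulation configuration. Confusion matrices may be written in
# full (five rows of five probabilities) or as an {accuracy: p} shorthand
# expanded by confusion_from_accuracy().
n_patients: 60
prevalence: [0.78, 0.12, 0.07, 0.02, 0.01]
inter_eye_concordance: 0.8
grader_confusions:
  grader1: {accuracy: 0.75}
  grader2: {accuracy: 0.92}
  grader3: {accuracy: 0.82}
quality_fail:
  grader1: 0.03
  grader2: 0.02
  grader3: 0.03
ai_confusion: {accuracy: 0.8}
ai_ungradable: 0.1
images_per_eye: [2, 3]
adjudication_policy: truth
seed: 42
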