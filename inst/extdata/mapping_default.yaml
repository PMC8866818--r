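mappings:
- source: dataset1
  header: SUBJECT_ID
  pattern_key: subject_id
  type: text
  min: ~
  max: ~
- source: dataset1
  header: GROUP
  pattern_key: group_label
  type: text
  min: ~
  max: ~
- source: dataset1
  header: SEX
  pattern_key: sex
  type: text
  min: ~
  max: ~
- source: dataset1
  header: AGE
  pattern_key: age_years
  type: decimal
  min: 0.0
  max: 120.0
- source: dataset1
  header: EDUCATION_YRS
  pattern_key: education_years
  type: decimal
  min: 0.0
  max: 30.0
- source: dataset1
  header: HOEHN_YAHR
  pattern_key: hoehn_yahr
  type: decimal
  min: 0.0
  max: 5.0
- source: dataset1
  header: MOCA_total
  pattern_key: moca_total
  type: integer
  min: 0.0
  max: 30.0
- source: dataset1
  header: MOCA_words_total
  pattern_key: moca_category_fluency
  type: integer
  min: 0.0
  max: 60.0
- source: dataset1
  header: LHIPPO_VOL_MM3
  pattern_key: volume_left_hippocampus
  type: decimal
  min: 0.0
  max: ~
- source: dataset1
  header: RHIPPO_VOL_MM3
  pattern_key: volume_right_hippocampus
  type: decimal
  min: 0.0
  max: ~
- source: dataset1
  header: ICV_MM3
  pattern_key: icv
  type: decimal
  min: 0.0
  max: ~
- source: dataset2
  header: PATNO
  pattern_key: subject_id
  type: text
  min: ~
  max: ~
- source: dataset2
  header: CONDX
  pattern_key: group_label
  type: text
  min: ~
  max: ~
- source: dataset2
  header: GENDER
  pattern_key: sex
  type: text
  min: ~
  max: ~
- source: dataset2
  header: AGE
  pattern_key: age_years
  type: decimal
  min: 0.0
  max: 120.0
- source: dataset2
  header: EDUCYRS
  pattern_key: education_years
  type: decimal
  min: 0.0
  max: 30.0
- source: dataset2
  header: NHY
  pattern_key: hoehn_yahr
  type: decimal
  min: 0.0
  max: 5.0
- source: dataset2
  header: MCATOT
  pattern_key: moca_total
  type: integer
  min: 0.0
  max: 30.0
- source: dataset2
  header: MCAVF
  pattern_key: moca_category_fluency
  type: integer
  min: 0.0
  max: 60.0
- source: dataset2
  header: HIPPL
  pattern_key: volume_left_hippocampus
  type: decimal
  min: 0.0
  max: ~
- source: dataset2
  header: HIPPR
  pattern_key: volume_right_hippocampus
  type: decimal
  min: 0.0
  max: ~
- source: dataset2
  header: EICV
  pattern_key: icv
  type: decimal
  min: 0.0
  max: ~
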