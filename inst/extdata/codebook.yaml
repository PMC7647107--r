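# Default codebook for the household water treatment (HWT) survey.
#
# Roles: id | sec | asset | ranas_item | behaviour_item.
# Scales: likert_1_5 | binary_0_1 | categorical (with ordered states) | count.
# polarity: negative marks reverse-coded items (flipped before PCA scoring).
# derived: true marks analysis variables that are not raw survey columns
# (the wealth index is built from the asset checklist).
variables:
  - name: household_id
    role: id

  # --- socio-economic characteristics -------------------------------------
  - name: health_problem
    role: sec
    scale: categorical
    states: ["No", "Yes"]
    label: diarrhea case among under-fives in the last two weeks
  - name: information_access
    role: sec
    scale: categorical
    states: [Difficult, Medium, Easy]
    label: access to mass media (frequency watching TV)
  - name: mother_education
    role: sec
    scale: categorical
    states: [None, Primary, Secondary, Higher]
  - name: father_education
    role: sec
    scale: categorical
    states: [None, Primary, Secondary, Higher]
  - name: wealth
    role: sec
    scale: categorical
    states: [Poor, Middle, Rich]
    derived: true
    label: asset-based wealth index, 40/40/20 split
  - name: religion
    role: sec
    scale: categorical
    states: [Christian, Islam]
  - name: accessibility
    role: sec
    scale: categorical
    states: [Difficult, Easy]
    label: physical accessibility of the dwelling
  - name: access_water
    role: sec
    scale: categorical
    states: [Far, Medium, Close]
    label: distance to the main water source

  # --- household asset checklist (wealth index inputs) ---------------------
  - name: asset_electricity
    role: asset
    scale: binary_0_1
  - name: asset_television
    role: asset
    scale: binary_0_1
  - name: asset_refrigerator
    role: asset
    scale: binary_0_1
  - name: asset_motorcycle
    role: asset
    scale: binary_0_1
  - name: asset_mobile_phone
    role: asset
    scale: binary_0_1
  - name: asset_own_toilet
    role: asset
    scale: binary_0_1
  - name: asset_tap_inside
    role: asset
    scale: binary_0_1
  - name: asset_bicycle
    role: asset
    scale: binary_0_1

  # --- RANAS psychological sub-factor items --------------------------------
  - name: perceived_vulnerability
    role: ranas_item
    factor: Risk
    scale: likert_1_5
  - name: health_knowledge
    role: ranas_item
    factor: Risk
    scale: likert_1_5
    label: number of correct preventive measures, mapped to 1-5
  - name: perceived_severity
    role: ranas_item
    factor: Risk
    scale: likert_1_5
  - name: health_benefit
    role: ranas_item
    factor: Attitude
    scale: likert_1_5
  - name: affective_taste
    role: ranas_item
    factor: Attitude
    scale: likert_1_5
  - name: affective_enjoy
    role: ranas_item
    factor: Attitude
    scale: likert_1_5
  - name: norm_descriptive
    role: ranas_item
    factor: Norm
    scale: likert_1_5
  - name: norm_injunctive
    role: ranas_item
    factor: Norm
    scale: likert_1_5
  - name: norm_personal
    role: ranas_item
    factor: Norm
    scale: likert_1_5
  - name: confidence_performance
    role: ranas_item
    factor: Ability
    scale: likert_1_5
  - name: confidence_recovering
    role: ranas_item
    factor: Ability
    scale: likert_1_5
  - name: confidence_continuation
    role: ranas_item
    factor: Ability
    scale: likert_1_5
  - name: action_control
    role: ranas_item
    factor: Self-regulation
    scale: likert_1_5
  - name: remembering
    role: ranas_item
    factor: Self-regulation
    scale: likert_1_5
    polarity: negative
    label: how often treating was forgotten (reverse coded)
  - name: commitment
    role: ranas_item
    factor: Self-regulation
    scale: likert_1_5
  - name: barrier_planning
    role: ranas_item
    factor: Self-regulation
    scale: binary_0_1
    label: 1 = has a clear solution to barriers, 0 = none

  # --- HWT behaviour items --------------------------------------------------
  - name: hwt_self_report
    role: behaviour_item
    scale: binary_0_1
    label: self-reported current treatment of drinking water
  - name: raw_water_frequency
    role: behaviour_item
    scale: likert_1_5
    polarity: negative
    label: frequency of drinking raw water daily (reverse coded)
  - name: water_treated_share
    role: behaviour_item
    scale: likert_1_5
    label: share of daily drinking water treated
  - name: hwt_habit
    role: behaviour_item
    scale: likert_1_5
  - name: hwt_intention
    role: behaviour_item
    scale: likert_1_5
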