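# Bundled reference scenario: rehabilitation of mandibular edentulism in the
# Brazilian Unified Health System (SUS) — conventional complete denture (CTP)
# vs two-implant-supported overdenture (ISTP). 2018 SIGTAP tariffs, BRL.
# Transition probabilities are given as printed (four decimals); two rows sum
# to 0.9999 and are proportionally renormalized on load.
states:
- id: A
  label: rehabilitated without complications
  absorbing: no
  utility_multiplier: 1.0
- id: B
  label: rehabilitated with repairable damage
  absorbing: no
  utility_multiplier: 0.75
- id: C
  label: treatment failure
  absorbing: no
  utility_multiplier: 0.5
- id: D
  label: non-treatment-related death
  absorbing: yes
  utility_multiplier: 0.0
strategies:
- name: CTP
  transition:
  - [0.1697, 0.5121, 0.3106, 0.0075]
  - [0.5403, 0.2231, 0.2291, 0.0075]
  - [0.0000, 0.0000, 0.9925, 0.0075]
  - [0.0000, 0.0000, 0.0000, 1.0000]
  costs:
    initial_cost: 196.83
    replacement_cost: 196.83
    replacement_interval: 5
  base_qapy: 0.79
- name: ISTP
  transition:
  - [0.9154, 0.0768, 0.0003, 0.0075]
  - [0.6519, 0.2909, 0.0496, 0.0075]
  - [0.0000, 0.0000, 0.9925, 0.0075]
  - [0.0000, 0.0000, 0.0000, 1.0000]
  costs:
    initial_cost: 1050.40
    replacement_cost: 1050.40
    replacement_interval: 5
  base_qapy: 0.94
settings:
  discount_rate_costs: 0.05
  discount_rate_effects: 0.05
  horizon: 20
  cycle_length: 1
  cohort_size: 1000000.0
  wtp_thresholds: [250.0, 450.0, 750.0, 3050.0]
initial_state: A
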