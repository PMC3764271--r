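# Six typical environment-domain interventions, one per sub-domain theme.
# Reach fractions for commuting-linked entries derive from the exemplar
# city's context statistics (commute 40%, public transport 38%, 5%
# institutional exceptions); numeric fields without a printed source are
# editable fixture defaults, not claims.
- name: cycling-infrastructure
  domain: environment
  sub_domain: transportation_systems
  reach_fraction: 0.52
  distal_impact: 1.0
  municipal_influence: 7
  effects:
    - {channel: exercise, intensity: 1.0, grade: strong}
  cost_effectiveness: 1.0
  notes: Commuter cycling network built at scale in year 1.
- name: walkable-neighbourhoods
  domain: environment
  sub_domain: built_environment
  reach_fraction: 0.95
  distal_impact: 0.6
  municipal_influence: 8
  effects:
    - {channel: exercise, intensity: 0.6, grade: strong}
    - {channel: stress, intensity: 0.3, grade: moderate}
  cost_effectiveness: 0.8
  notes: >
    High-walkability urban design; residents of highly walkable
    neighbourhoods walk more, with community-level hypertension benefits.
    Eligibility excludes the 5% in institutions or housebound.
- name: urban-green-space
  domain: environment
  sub_domain: natural_environment
  reach_fraction: 0.95
  distal_impact: 0.5
  municipal_influence: 9
  effects:
    - {channel: exercise, intensity: 0.4, grade: moderate}
    - {channel: stress, intensity: 0.5, grade: strong}
  cost_effectiveness: 0.7
  notes: Parks and green-space provision; fresh air and raised spirits
    benefit all ages.
- name: air-quality-road-transport
  domain: environment
  sub_domain: transportation_systems
  reach_fraction: 1.0
  distal_impact: 0.4
  municipal_influence: 6
  effects:
    - {channel: air_quality, intensity: 1.0, grade: strong}
  cost_effectiveness: 0.6
  notes: Regulation of road-transport air pollution, the dominant urban
    source.
- name: public-transport-walk-access
  domain: environment
  sub_domain: transportation_systems
  reach_fraction: 0.152
  distal_impact: 0.8
  municipal_influence: 7
  effects:
    - {channel: exercise, intensity: 0.5, grade: strong}
  cost_effectiveness: 0.9
  notes: Walking home from the public transport stop; reach = commute 40%
    times public-transport share 38%.
- name: industrial-zoning-and-noise
  domain: environment
  sub_domain: built_environment
  reach_fraction: 0.30
  distal_impact: 0.3
  municipal_influence: 8
  effects:
    - {channel: stress, intensity: 0.6, grade: moderate}
    - {channel: air_quality, intensity: 0.3, grade: moderate}
  cost_effectiveness: 0.5
  notes: Zoning industry away from housing and regulating noise pollution.
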