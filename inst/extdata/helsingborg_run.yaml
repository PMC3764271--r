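# Helsingborg-style commuter cycling scenario: city of circa 100,000;
# 52% of residents are cyclists or potential cyclists; the investment is
# largely (70%) controlled by the municipality; assessed on strong evidence
# as 100% cost-effective at increasing physical activity; built at scale in
# year 1 and evaluated over a 5-year period.
name: helsingborg-cycling
population:
  generate:
    total_population: 100000
    seed: 20
    name: helsingborg-like
interventions:
  - name: helsingborg-cycling-infrastructure
    domain: environment
    sub_domain: transportation_systems
    reach_fraction: 0.52
    distal_impact: 1.0
    municipal_influence: 7
    effects:
      - channel: exercise
        intensity: 1.0
        grade: strong
    cost_effectiveness: 1.0
    notes: Commuter cycling infrastructure built at scale in year 1.
horizon: 5
seed: 20
discount_rate: 0
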