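# Sheffield-like exemplar city: population 530,000, all ages.
# Context statistics for building reach fractions (commuting interventions):
#   working age 64%; economically active 52%; travel/commute to work 40%;
#   modal split: car 53%, public transport 38%, walk 8%, cycle 0.6%;
#   institutional/housebound exceptions: 5% (eligibility 0.95).
name: sheffield-like
population:
  generate:
    total_population: 530000
    seed: 11
    name: sheffield-like
horizon: 5
seed: 11
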