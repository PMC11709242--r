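# SYNTHETIC reference daily-intake table for testing the recommendation
# pipeline. Values are round numbers in a plausible order of magnitude for
# the six compositional elements; they are NOT clinical guidance.
nutrients:
  - nutrient: Potassium
    unit: mg
    requirements:
      - {sex: female, age_min: 18, age_max: 51, daily: 2600}
      - {sex: female, age_min: 51, age_max: 120, daily: 2600}
      - {sex: male, age_min: 18, age_max: 51, daily: 3400}
      - {sex: male, age_min: 51, age_max: 120, daily: 3400}
  - nutrient: Calcium
    unit: mg
    requirements:
      - {sex: female, age_min: 18, age_max: 51, daily: 1000}
      - {sex: female, age_min: 51, age_max: 120, daily: 1200}
      - {sex: male, age_min: 18, age_max: 71, daily: 1000}
      - {sex: male, age_min: 71, age_max: 120, daily: 1200}
  - nutrient: Fiber
    unit: g
    requirements:
      - {sex: female, age_min: 18, age_max: 51, daily: 25}
      - {sex: female, age_min: 51, age_max: 120, daily: 21}
      - {sex: male, age_min: 18, age_max: 51, daily: 38}
      - {sex: male, age_min: 51, age_max: 120, daily: 30}
  - nutrient: Protein
    unit: g
    requirements:
      - {sex: female, age_min: 18, age_max: 120, daily: 46}
      - {sex: male, age_min: 18, age_max: 120, daily: 56}
  - nutrient: Fat
    unit: g
    requirements:
      - {sex: female, age_min: 18, age_max: 120, daily: 70}
      - {sex: male, age_min: 18, age_max: 120, daily: 80}
  - nutrient: Iron
    unit: mg
    requirements:
      - {sex: female, age_min: 18, age_max: 51, daily: 18}
      - {sex: female, age_min: 51, age_max: 120, daily: 8}
      - {sex: male, age_min: 18, age_max: 120, daily: 8}
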