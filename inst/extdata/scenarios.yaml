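# Packaged behavior-change scenarios: each moves individuals one step
# toward the desirable end of the behavior; top levels map to themselves.
- name: Increase Physical Activity
  transforms:
    activity_level: [2, 3, 4, 4]
- name: Eliminate Smoking & Secondhand Smoking
  transforms:
    smoke: [0, 0]
    secsmoke: [0, 0]
- name: Increase Fruit & Vegetable Consumption
  transforms:
    fruit: [2, 3, 4, 5, 5]
    veg: [2, 3, 4, 5, 5]
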