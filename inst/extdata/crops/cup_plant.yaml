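# Surrogate-engine parameter set (stand-in calibration, not a crop model claim)
crop: cup_plant
pathway: C3
season: [4, 5, 6, 7, 8, 9]
max_monthly_growth: 4.9
temp_base: 5.0
temp_optimum: 16.0
crop_coefficient: 1.15
harvest_index: 1.0        # perennial, whole-plant harvest from year two
yield_ceiling: 30
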