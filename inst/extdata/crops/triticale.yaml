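# Surrogate-engine parameter set (stand-in calibration, not a crop model claim)
crop: triticale
pathway: C3
season: [10, 11, 12, 1, 2, 3, 4, 5, 6]
max_monthly_growth: 6.3
temp_base: 3.0
temp_optimum: 15.0
crop_coefficient: 0.85
harvest_index: 1.0        # whole-plant harvest for biogas
yield_ceiling: 45
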