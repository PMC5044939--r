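# Surrogate-engine parameter set (stand-in calibration, not a crop model claim)
crop: maize
pathway: C4
season: [5, 6, 7, 8, 9]
max_monthly_growth: 6.0   # t DM/ha per month at optimum
temp_base: 8.0            # deg C
temp_optimum: 16.0        # deg C
crop_coefficient: 1.10
harvest_index: 1.0        # whole-plant silage harvest
yield_ceiling: 32
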