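# Shared fixtures, built once per test run. Sizes are kept small: the
# data-unit grid is the full 175, but the soil map is 600 records and the
# engine runs all four crops over the 27 synthetic years (about 2 s).
fix_cfg <- synthetic_config(seed = 7, n_units = 600)
fix_regions <- synthetic_regions(fix_cfg)
fix_daily <- gen_daily_climate(fix_cfg)
fix_monthly <- aggregate_daily_to_monthly(fix_daily)
fix_units <- build_data_units(regions = fix_regions$region_id)
fix_crops <- crop_parameters()
fix_sim <- run_units(fix_units, fix_monthly, fix_crops, fix_cfg$years,
                     fix_regions)

# a fixed one-season climate fixture (season months of maize, mild summer)
fix_season_climate <- tibble::tibble(
  month = 1:12,
  t_mean = c(1, 2, 5, 9, 13, 16, 18, 17, 14, 10, 5, 2),
  precip_sum = c(50, 40, 50, 45, 55, 65, 65, 60, 50, 48, 52, 58)
)
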