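# Example pipeline configuration. Every protocol constant is a default
# of pipeline_config(); this file only overrides what a run changes.
# input: path/to/panel.csv
# output_dir: results/run1
outcome: HLI
directions:
  incidence_ab: negative
  mortality_ab: negative
  human_mortality: negative
  life_expectancy: positive
families: [xgboost, gbdt, hist_gbdt, adaboost, random_forest, lasso]
primary_family: xgboost
train_fraction: 0.8
seed: 2025
k: 5
span: 0.3
n_boot: 1000
level: 0.95
threshold_top: 6
pdp_top: 4
pdp_grid_n: 20
attribution_rows: full
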