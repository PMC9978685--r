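# Example run configuration. File paths are resolved relative to the
# working directory; point them at the synthetic tables shipped in this
# folder (see README) or at your own summary-statistic files. All tables
# here are synthetic, generated by tidymr::simulate_study().
exposure:
  name: caffeine
  file: synthetic_caffeine_exposure.tsv
  select_per_locus: true
outcomes:
  - name: t2d_study1
    file: synthetic_t2d_study1.tsv
    binary: true
    group: t2d
  - name: t2d_study2
    file: synthetic_t2d_study2.tsv
    binary: true
    group: t2d
options:
  wald_order: first
  ivw_model: fixed
  n_outcomes: 8
  alpha: 0.05
  seed: 1
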