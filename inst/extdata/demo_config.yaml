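# Demo experiment: one site, three thinning regimes on 0.25 ha plots,
# climate 1957-2016 with two mild (1984, 1991) and two severe (2003, 2011)
# embedded drought years.
seed: 1
regimes: [control, slow, medium]
synthetic:
  n_sites: 1
  years: [1957, 2016]
  growth_years: [1980, 2016]
  plot_side: 50
  stem_density: 600
  drought_years:
    "1984": 0.75
    "1991": 0.78
    "2003": 0.45
    "2011": 0.55
analysis:
  window: 2
  ni_radius: 10
  spei_month: 7
  spei_scale: 5
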