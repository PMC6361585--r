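{
  "required": ["provenance", "qc", "profiles", "classification",
               "proportions", "correlations"],
  "columns": {
    "qc": ["unit_id", "refractory_violation_fraction", "drift_statistic",
           "drift_p", "accepted", "reasons"],
    "profiles": ["unit_id", "stimulus", "win_start", "win_end",
                 "direction", "p_value", "magnitude", "latency"],
    "classification": ["unit_id", "valence_encoding", "cell_type",
                       "footshock_response_type"]
  },
  "provenance": ["package", "version", "seed", "alpha", "windows",
                 "method", "sd_floor", "n_units", "n_accepted"]
}
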