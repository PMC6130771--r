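{
  "stages": ["pm1", "e1", "e2", "m1", "l1", "l2"],
  "tei_omega0_log2": {
    "pm1": 0.123570510230302,
    "e1": 0.115278970525573,
    "e2": 0.11634170428636,
    "m1": 0.119870985361989,
    "l1": 0.146757849471387,
    "l2": 0.168351522556227
  },
  "tei_phylostratum_log2": {
    "pm1": 2.43266083668363,
    "e1": 2.26798273310266,
    "e2": 2.33390023772055,
    "m1": 2.50826163603686,
    "l1": 3.18253568151397,
    "l2": 3.69067522077236
  },
  "delta_em_omega0": -0.00406064795602261,
  "delta_em_phylostratum": -0.207320150625256,
  "pleiotropy": {
    "n_expressed": {
      "pm1": 5,
      "e1": 8,
      "e2": 10,
      "m1": 10,
      "l1": 8,
      "l2": 7
    },
    "n_pleiotropic": {
      "pm1": 4,
      "e1": 6,
      "e2": 8,
      "m1": 8,
      "l1": 7,
      "l2": 6
    },
    "proportion": {
      "pm1": 0.8,
      "e1": 0.75,
      "e2": 0.8,
      "m1": 0.8,
      "l1": 0.875,
      "l2": 0.857142857142857
    },
    "chi2": 0.0989010989010989,
    "df": 5,
    "p_value": 0.999842044167499,
    "flagged": ["g01", "g03", "g05", "g06", "g07", "g09", "g10", "g_const"]
  },
  "tau": {
    "g01": 0.208333333333333,
    "g02": 0.208333333333333,
    "g03": 0.875,
    "g04": 0.2,
    "g05": 0.166666666666667,
    "g06": 0.166666666666667,
    "g07": 1,
    "g08": 0.96875,
    "g09": 0.75,
    "g10": 0,
    "g11": 1,
    "g_const": 0.65625
  },
  "testis_specific": ["g07", "g08", "g11"],
  "retrogene": {
    "medians_all": {
      "pm1": 0.25,
      "e1": 0.75,
      "e2": 1.5,
      "m1": 3,
      "l1": 8,
      "l2": 12
    },
    "rho_all": 1,
    "medians_excl_testis": {
      "pm1": 1,
      "e1": 1,
      "e2": 2,
      "m1": 4,
      "l1": 8,
      "l2": 16
    },
    "rho_excl_testis": 0.985610760609162,
    "n_after_exclusion": 1
  }
}
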