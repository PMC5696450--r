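{
  "provenance": "published",
  "description": "Published multiple-linear-regression descriptive models predicting CYP kinetic parameters in human liver microsomes (n = 105) from measured CYP activities. Predictors use the same kinetic parameter as the response. Units: vmax pmol/min/mg protein, km uM, clint ul/min/mg protein.",
  "models": [
    {
      "cyp": "2A6", "parameter": "vmax", "intercept": 104.899,
      "terms": [{"cyp": "2C19", "coef": 2.292}],
      "n": 105, "f_stat": 21.559, "p_value": 1.015e-05, "r2": 0.173, "r2_adj": 0.165
    },
    {
      "cyp": "2D6", "parameter": "vmax", "intercept": 10.698,
      "terms": [{"cyp": "2C9", "coef": 0.481}],
      "n": 105, "f_stat": 12.655, "p_value": 5.677e-04, "r2": 0.109, "r2_adj": 0.101
    },
    {
      "cyp": "2E1", "parameter": "vmax", "intercept": 362.868,
      "terms": [{"cyp": "1A2", "coef": 0.290}],
      "n": 105, "f_stat": 25.152, "p_value": 2.217e-06, "r2": 0.196, "r2_adj": 0.188
    },
    {
      "cyp": "2C8", "parameter": "vmax", "intercept": -6.784,
      "terms": [{"cyp": "2C9", "coef": 0.158}, {"cyp": "2B6", "coef": 0.143}],
      "n": 105, "f_stat": 24.813, "p_value": 1.656e-09, "r2": 0.327, "r2_adj": 0.314
    },
    {
      "cyp": "3A4/5", "parameter": "vmax", "intercept": 106.151,
      "terms": [{"cyp": "2B6", "coef": 9.416}, {"cyp": "2C19", "coef": 2.504}],
      "n": 105, "f_stat": 21.209, "p_value": 1.985e-08, "r2": 0.294, "r2_adj": 0.280
    },
    {
      "cyp": "3A4/5", "parameter": "km", "intercept": 2.941,
      "terms": [{"cyp": "1A2", "coef": -0.013}],
      "n": 105, "f_stat": 7.641, "p_value": 6.762e-03, "r2": 0.069, "r2_adj": 0.060
    },
    {
      "cyp": "2A6", "parameter": "clint", "intercept": 120.384,
      "terms": [{"cyp": "2C19", "coef": 9.662}],
      "n": 105, "f_stat": 4.381, "p_value": 3.881e-02, "r2": 0.041, "r2_adj": 0.031
    },
    {
      "cyp": "2C8", "parameter": "clint", "intercept": 1.693,
      "terms": [{"cyp": "2C9", "coef": 0.862}],
      "n": 105, "f_stat": 31.661, "p_value": 1.590e-07, "r2": 0.235, "r2_adj": 0.228
    },
    {
      "cyp": "2D6", "parameter": "clint", "intercept": 3.325,
      "terms": [{"cyp": "2B6", "coef": 1.438}],
      "n": 105, "f_stat": 5.250, "p_value": 2.399e-02, "r2": 0.048, "r2_adj": 0.039
    },
    {
      "cyp": "2E1", "parameter": "clint", "intercept": 6.414,
      "terms": [{"cyp": "2C19", "coef": 1.218}, {"cyp": "1A2", "coef": 0.143}],
      "n": 105, "f_stat": 11.108, "p_value": 4.319e-05, "r2": 0.179, "r2_adj": 0.163
    },
    {
      "cyp": "3A4/5", "parameter": "clint", "intercept": 407.070,
      "terms": [{"cyp": "2C19", "coef": 77.635}, {"cyp": "1A2", "coef": -8.003}, {"cyp": "2B6", "coef": 87.331}],
      "n": 105, "f_stat": 7.257, "p_value": 1.858e-04, "r2": 0.177, "r2_adj": 0.153
    }
  ]
}
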