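{
  "schema_version": "1.0",
  "model": {
    "p": 6,
    "m": 2,
    "variables": ["X1", "X2", "X3", "X4", "X5", "X6"],
    "factors": ["f1", "f2"],
    "loadings": {
        "X1": [0.64, 0.37],
        "X2": [0.34, 0.54],
        "X3": [0.46, 0.76],
        "X4": [0.25, 0.41],
        "X5": [0.97, -0.12],
        "X6": [0.82, -0.03]
      },
    "factor_corr": {
        "f1": [1, 0],
        "f2": [0, 1]
      },
    "uniqueness": {
      "X1": 0.4535,
      "X2": 0.5928,
      "X3": 0.2108,
      "X4": 0.7694,
      "X5": 0.0447000000000001,
      "X6": 0.3267
    }
  },
  "contributions": {
    "total_kl": 29.3678051315245,
    "per_variable": {
      "X1": 1.20507166482911,
      "X2": 0.686909581646424,
      "X3": 3.7438330170778,
      "X4": 0.299714062906161,
      "X5": 21.3713646532438,
      "X6": 2.06091215182124
    },
    "per_group": {
      "g": 1.20507166482911,
      "problem": 4.73045666163038,
      "verbal": 23.4322768050651
    },
    "per_factor": {
      "f1": 25.2906056300193,
      "f2": 4.07719950150521
    },
    "ecd": 0.967070389326165,
    "rc": {
      "f1": 0.861167714671036,
      "f2": 0.138832285328964
    },
    "rc_tilde": {
      "f1": 0.832809797102043,
      "f2": 0.134260592224122
    }
  }
}
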