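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
  "subgroups": {
    "g": {
      "subset": 1,
      "rho_sq": 0.5465,
      "contributions": 1.20507166482911,
      "factor_coefs": {
        "eta1": [0.865734831114128, 0.500502949237855]
      },
      "manifest_coefs": {
        "V1": 1
      },
      "total_kl": 1.20507166482911,
      "rc": 1,
      "rc_tilde": 0.5465,
      "capped": false
    },
    "problem": {
      "subset": [2, 3, 4],
      "rho_sq": [0.825488334741683, 0.000180669952992822],
      "contributions": [4.73027595902986, 0.000180702600523164],
      "factor_coefs": {
        "eta1": [0.520169810096676, 0.854062859902003],
        "eta2": [0.854062859902003, -0.520169810096676]
      },
      "manifest_coefs": {
        "V1": [0.206736259319601, 0.80945043160553, 0.119879909105444],
        "V2": [1.19075305210148, -0.868096089570786, 0.0237916932676589]
      },
      "total_kl": 4.73045666163038,
      "rc": [0.999961800178408, 3.81998215920413e-05],
      "rc_tilde": [0.825462304025879, 3.15337173271199e-05],
      "capped": [false, false]
    },
    "verbal": {
      "subset": [5, 6],
      "rho_sq": [0.9590469973222, 0.0138483923221298],
      "contributions": [23.4182339416612, 0.0140428634038727],
      "factor_coefs": {
        "eta1": [0.993336690286077, -0.11524851292534],
        "eta2": [0.11524851292534, 0.993336690286077]
      },
      "manifest_coefs": {
        "V1": [0.914356783772951, 0.104704788767752],
        "V2": [-1.38904501207487, 1.65967806541232]
      },
      "total_kl": 23.4322768050651,
      "rc": [0.999400704271263, 0.000599295728737605],
      "rc_tilde": [0.958495768875963, 0.000574766875634018],
      "capped": [false, false]
    }
  }
}
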