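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
  "cca": {
    "subset": [1, 2, 3, 4, 5, 6],
    "rho_sq": [0.961963811915371, 0.803035336355514],
    "contributions": [25.2907523165843, 4.07705281494025],
    "factor_coefs": {
      "eta1": [0.99999654263938, -0.00262958348168271],
      "eta2": [0.00262958348168271, 0.99999654263938]
    },
    "manifest_coefs": {
      "V1": [0.0546459611174763, 0.0221497714205856, 0.0842582472041773, 0.0125466269488161, 0.84182454855738, 0.09734700948402],
      "V2": [0.180141935487287, 0.200550388437185, 0.793694090119367, 0.117313220800533, -0.577513819430572, -0.0187325901899883]
    },
    "total_kl": 29.3678051315245,
    "rc": [0.861172709479613, 0.138827290520386],
    "rc_tilde": [0.832814627433518, 0.134255761892647],
    "capped": [false, false]
  }
}
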