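{
  "schema_version": "1.0",
  "model": {
    "p": 5,
    "m": 2,
    "variables": ["X1", "X2", "X3", "X4", "X5"],
    "factors": ["f1", "f2"],
    "loadings": {
        "X1": [0.6, 0.39],
        "X2": [0.75, 0.24],
        "X3": [0.65, 0],
        "X4": [0.32, 0.59],
        "X5": [0, 0.92]
      },
    "factor_corr": {
        "f1": [1, 0],
        "f2": [0, 1]
      },
    "uniqueness": {
      "X1": 0.4879,
      "X2": 0.3799,
      "X3": 0.5775,
      "X4": 0.5495,
      "X5": 0.1536
    }
  },
  "derived": {
    "coef_matrix": {
        "arts": [0.946983736695709, 0.321281500298153],
        "science": [0.0573869202667532, 0.998352012760177]
      },
    "new_loadings": {
        "X1": [0.622048721034599, 0.190461131161293],
        "X2": [0.79288288715494, -0.0147629326705332],
        "X3": [0.700041827692794, -0.225281750122168],
        "X4": [0.30811083869657, 0.491820200900816],
        "X5": [-0.056954452495984, 0.939847268252031]
      },
    "factor_corr_new": {
        "arts": [1, 0.375096512676939],
        "science": [0.375096512676939, 1]
      },
    "contributions_full": {
      "arts": 4.28394491444371,
      "science": 6.74445085936973
    },
    "contributions_groups": {
      "arts": {
        "contributions": [3.27357420349563, 0.580799369434278],
        "rc": [0.959015501989138, 0.170149067718768]
      },
      "science": {
        "contributions": [1.01037071094808, 6.16365148993546],
        "rc": [0.159609849697419, 0.973681716261097]
      }
    },
    "uniqueness": {
      "X1": 0.4879,
      "X2": 0.3799,
      "X3": 0.5775,
      "X4": 0.5495,
      "X5": 0.1536
    }
  }
}
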