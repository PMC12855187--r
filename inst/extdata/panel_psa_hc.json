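{
  "name": "psa_hc_discovery_panel",
  "description": "Nine-metabolite logistic biomarker panel distinguishing healthy controls (coded y = 1, confirmed by evaluating the formula at the two group mean vectors) from active PsA patients, on the relative-concentration scale. Published coefficients and decision threshold.",
  "positive_class": "HC",
  "intercept": -61.645,
  "threshold": 0.38,
  "coefficients": {
    "leucine": 2.991,
    "serine": 2.08,
    "alanine": 1.735,
    "glucose": 0.394,
    "methionine": 6.134,
    "isoleucine": -0.313,
    "valine": -0.072,
    "glycylproline": 0.256,
    "glutamine": 0.346
  }
}
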