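{
  "scale": 1.0,
  "entries": {
    "family_history_ckd": {
      "kind": "binary",
      "prevalence": 0.218,
      "hr": 2.04,
      "source": "REGARDS cohort (McClellan 2012), incident ESRD"
    },
    "nsaid_chronic": {
      "kind": "binary",
      "prevalence": 0.30,
      "hr": 1.32,
      "source": "NHIRD Taiwan (Hsu 2015), NSAID exposure >=90 days/year"
    },
    "dr_severity": {
      "kind": "ordinal",
      "prevalence": [0.50, 0.20, 0.15, 0.10, 0.05],
      "hr": [2.9, 5.8, 10.2, 16.6],
      "source": "DR severity ladder (Li 2021 meta-analysis); prevalence Hsing 2021"
    },
    "imd_quintile": {
      "kind": "quintile",
      "prevalence": [0.20, 0.20, 0.20, 0.20, 0.20],
      "hr": 1.05,
      "se": 0.05,
      "source": "UK CPRD deprivation quintiles (Weldegiorgis 2024); modest per-quintile gradient"
    },
    "sglt2i": {
      "kind": "binary",
      "prevalence": 0.30,
      "hr": 0.61,
      "ci": [0.55, 0.67],
      "source": "CREDENCE/DAPA-CKD pooled"
    },
    "ace_arb": {
      "kind": "binary",
      "prevalence": 0.55,
      "hr": 0.77,
      "ci": [0.71, 0.83],
      "source": "RENAAL/IDNT"
    },
    "glp1_ra": {
      "kind": "binary",
      "prevalence": 0.15,
      "hr": 0.79,
      "ci": [0.73, 0.85],
      "source": "FLOW trial"
    },
    "finerenone": {
      "kind": "binary",
      "prevalence": 0.05,
      "hr": 0.82,
      "ci": [0.76, 0.88],
      "source": "FIDELIO-DKD"
    },
    "statin": {
      "kind": "binary",
      "prevalence": 0.60,
      "hr": 0.88,
      "ci": [0.84, 0.92],
      "source": "Chinese T2D cohort (Zhou 2023) harmonised"
    }
  }
}
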