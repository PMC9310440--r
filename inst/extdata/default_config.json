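{
  "priors": {
    "markers": {
      "ht": 0.2,
      "os": 0.275,
      "ob": 0.034,
      "dp": 0.132,
      "pa": 0.177,
      "drp1": 0.743,
      "opa1": 0.614,
      "mfn1": 0.278,
      "mfn2": 0.336,
      "fis1": 0.6
    },
    "age_brackets": [
      {
        "min": 30,
        "max": 64,
        "p": 0.04
      },
      {
        "min": 65,
        "max": 74,
        "p": 0.15
      },
      {
        "min": 75,
        "max": 84,
        "p": 0.43
      },
      {
        "min": 85,
        "max": 95,
        "p": 0.38
      }
    ],
    "default_prior": 0.5,
    "age_range": [30, 95]
  },
  "network": {
    "nodes": ["age", "diet", "atp", "opa1", "mfn1", "mfn2", "drp1", "fis1", "db", "os", "ht", "ob", "dp", "pa", "fusion", "fission", "AD"],
    "edges": [
      {
        "parent": "diet",
        "child": "os",
        "sign": "deterrent"
      },
      {
        "parent": "diet",
        "child": "ob",
        "sign": "promoting"
      },
      {
        "parent": "diet",
        "child": "atp",
        "sign": "promoting"
      },
      {
        "parent": "diet",
        "child": "opa1",
        "sign": "promoting"
      },
      {
        "parent": "diet",
        "child": "mfn1",
        "sign": "promoting"
      },
      {
        "parent": "diet",
        "child": "mfn2",
        "sign": "promoting"
      },
      {
        "parent": "diet",
        "child": "drp1",
        "sign": "promoting"
      },
      {
        "parent": "diet",
        "child": "fis1",
        "sign": "promoting"
      },
      {
        "parent": "opa1",
        "child": "fusion",
        "sign": "promoting"
      },
      {
        "parent": "mfn1",
        "child": "fusion",
        "sign": "promoting"
      },
      {
        "parent": "mfn2",
        "child": "fusion",
        "sign": "promoting"
      },
      {
        "parent": "drp1",
        "child": "fission",
        "sign": "promoting"
      },
      {
        "parent": "fis1",
        "child": "fission",
        "sign": "promoting"
      },
      {
        "parent": "fusion",
        "child": "AD",
        "sign": "deterrent"
      },
      {
        "parent": "fission",
        "child": "AD",
        "sign": "promoting"
      },
      {
        "parent": "atp",
        "child": "AD",
        "sign": "deterrent"
      },
      {
        "parent": "db",
        "child": "AD",
        "sign": "promoting"
      },
      {
        "parent": "os",
        "child": "AD",
        "sign": "promoting"
      },
      {
        "parent": "ht",
        "child": "AD",
        "sign": "promoting"
      },
      {
        "parent": "ob",
        "child": "AD",
        "sign": "promoting"
      },
      {
        "parent": "dp",
        "child": "AD",
        "sign": "promoting"
      },
      {
        "parent": "pa",
        "child": "AD",
        "sign": "deterrent"
      },
      {
        "parent": "age",
        "child": "AD",
        "sign": "promoting"
      }
    ],
    "cpt_overrides": []
  },
  "diet_modifiers": {
    "HFO": {
      "os": 0.5,
      "mfn2": 2,
      "atp": 2
    },
    "HL": {
      "fis1": 2,
      "ob": 2,
      "mfn2": 0.5
    },
    "starv": {
      "mfn1": 2,
      "opa1": 2,
      "atp": 2
    },
    "CR": {
      "fis1": 2,
      "drp1": 2
    },
    "none": []
  },
  "simulation": {
    "n": 1000,
    "seed": 1,
    "age_min": 30,
    "age_max": 95,
    "diets": ["HFO", "HL", "starv", "CR", "none"]
  },
  "case_rule": {
    "marker_priority": ["opa1", "mfn2", "mfn1", "drp1", "fis1"],
    "lifestyle_set": ["ht", "dp", "ob", "pa", "os"],
    "no_diet_baseline": 0.743
  }
}
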