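{
  "voluntary": {
    "likert_summary": {
      "wave": [1, 2],
      "n": [50, 50],
      "mean": [2.84, 2.74],
      "ci_lo": [2.4798608695, 2.373602366],
      "ci_hi": [3.2001391305, 3.106397634],
      "ge4": [0.42, 0.36],
      "ge3": [0.7, 0.68],
      "ge2": [0.78, 0.8],
      "ge1": [0.94, 0.9]
    },
    "transitions": {
      "share_withdrew_among_prior_supporters": 0.14285714286,
      "share_became_supporters_among_prior_nonsupporters": 0.26666666667,
      "share_reduced_any": 0.34,
      "share_increased_any": 0.26
    },
    "share_level0": {
      "wave1": 0.06,
      "wave2": 0.1
    },
    "regressions": {
      "A": {
        "outcome": "agree_voluntary@wave2",
        "model_id": "A",
        "n": 50,
        "robust": false,
        "coefficients": {
          "term": ["trust", "altruism", "female", "east", "pandemic_critical"],
          "estimate": [-0.13039045046, 0.13587945123, 0.0061545182846, 0.1455866877, -0.0028350971089],
          "se": [0.15087588919, 0.15479369213, 0.15367117476, 0.16123671055, 0.15737356295],
          "ci_lo": [-0.43446082529, -0.17608673662, -0.30354938445, -0.17936455054, -0.32000067296],
          "ci_hi": [0.17367992437, 0.44784563908, 0.31585842102, 0.47053792595, 0.31433047874]
        }
      },
      "B": {
        "outcome": "agree_voluntary@wave2",
        "model_id": "B",
        "n": 50,
        "robust": false,
        "coefficients": {
          "term": ["trust", "altruism", "female", "east", "pandemic_critical", "effectiveness", "freedom"],
          "estimate": [-0.062861998071, 0.10493608955, 0.046945292552, 0.12460443183, 0.013990613055, 0.15144698881, 0.31373061722],
          "se": [0.15620405893, 0.15288234465, 0.15110370076, 0.15842679347, 0.1536411395, 0.1510205692, 0.15438222955],
          "ci_lo": [-0.3780945513, -0.20359297288, -0.25799432118, -0.19511378131, -0.29606975937, -0.15332485864, 0.0021746645218],
          "ci_hi": [0.25237055516, 0.41346515198, 0.35188490628, 0.44432264497, 0.32405098549, 0.45621883627, 0.62528656992]
        }
      },
      "C": {
        "outcome": "d_agree_voluntary",
        "model_id": "C",
        "n": 50,
        "robust": false,
        "coefficients": {
          "term": ["d_trust"],
          "estimate": [0.17006641299],
          "se": [0.14223494466],
          "ci_lo": [-0.1159161105],
          "ci_hi": [0.45604893647]
        }
      }
    }
  },
  "enforced": {
    "likert_summary": {
      "wave": [1, 2],
      "n": [50, 50],
      "mean": [2.64, 1.82],
      "ci_lo": [2.210739487, 1.4096761617],
      "ci_hi": [3.069260513, 2.2303238383],
      "ge4": [0.44, 0.22],
      "ge3": [0.62, 0.32],
      "ge2": [0.78, 0.52],
      "ge1": [0.8, 0.76]
    },
    "transitions": {
      "share_withdrew_among_prior_supporters": 0.54838709677,
      "share_became_supporters_among_prior_nonsupporters": 0.10526315789,
      "share_reduced_any": 0.52,
      "share_increased_any": 0.2
    },
    "share_level0": {
      "wave1": 0.2,
      "wave2": 0.24
    },
    "regressions": {
      "A": {
        "outcome": "agree_enforced@wave2",
        "model_id": "A",
        "n": 50,
        "robust": false,
        "coefficients": {
          "term": ["trust", "altruism", "female", "east", "pandemic_critical"],
          "estimate": [0.023794162383, -0.023785418275, -0.15220491909, -0.08003200727, 0.13237736927],
          "se": [0.15172917753, 0.15566913787, 0.15454027202, 0.16214859519, 0.15826359931],
          "ci_lo": [-0.28199590211, -0.33751595107, -0.46366037227, -0.40682102825, -0.186581957],
          "ci_hi": [0.32958422688, 0.28994511452, 0.15925053409, 0.24675701371, 0.45133669554]
        }
      },
      "B": {
        "outcome": "agree_enforced@wave2",
        "model_id": "B",
        "n": 50,
        "robust": false,
        "coefficients": {
          "term": ["trust", "altruism", "female", "east", "pandemic_critical", "effectiveness", "freedom"],
          "estimate": [-0.1256835884, 0.053745701184, -0.14088605655, -0.012879607309, 0.088328813098, 0.24124322093, -0.31478061331],
          "se": [0.15133266817, 0.14811454511, 0.14639137013, 0.15348608436, 0.14884967613, 0.14631083112, 0.14956765449],
          "ci_lo": [-0.43108527708, -0.24516155223, -0.43631580206, -0.32262706579, -0.21206199477, -0.054023990274, -0.61662036018],
          "ci_hi": [0.17971810028, 0.3526529546, 0.15454368896, 0.29686785117, 0.38871962097, 0.53651043213, -0.01294086644]
        }
      },
      "C": {
        "outcome": "d_agree_enforced",
        "model_id": "C",
        "n": 50,
        "robust": false,
        "coefficients": {
          "term": ["d_trust"],
          "estimate": [0.1005984364],
          "se": [0.14360535872],
          "ci_lo": [-0.18813948923],
          "ci_hi": [0.38933636203]
        }
      }
    }
  },
  "gap_pp": 36
}
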