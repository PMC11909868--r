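[
  {
    "name": "c_algo",
    "label": "Machine-learning algorithm fee",
    "base": 5000,
    "low": 500,
    "high": 10000,
    "family": "lognormal",
    "parameterization": "mean_median",
    "g1": 5000,
    "g2": 4900,
    "psa_fixed": false
  },
  {
    "name": "c_classifier",
    "label": "Genomic classifier fee",
    "base": 5793,
    "low": 500,
    "high": 10000,
    "family": "lognormal",
    "parameterization": "mean_median",
    "g1": 5793,
    "g2": 5500,
    "psa_fixed": false
  },
  {
    "name": "c_bronch",
    "label": "Bronchoscopy",
    "base": 11170,
    "low": 872,
    "high": 35039,
    "family": "lognormal",
    "parameterization": "mean_median",
    "g1": 11170,
    "g2": 5689,
    "psa_fixed": false
  },
  {
    "name": "c_slb",
    "label": "Surgical lung biopsy",
    "base": 42373,
    "low": 27048,
    "high": 57698,
    "family": "lognormal",
    "parameterization": "mean_median",
    "g1": 42373,
    "g2": 34482,
    "psa_fixed": false
  },
  {
    "name": "c_symptom",
    "label": "Lifetime symptom management",
    "base": 84073,
    "low": 10000,
    "high": 120000,
    "family": "lognormal",
    "parameterization": "mean_median",
    "g1": 84073,
    "g2": 72000,
    "psa_fixed": false
  },
  {
    "name": "c_treat",
    "label": "Lifetime nintedanib treatment",
    "base": 711579,
    "low": 100000,
    "high": 900000,
    "family": "lognormal",
    "parameterization": "mean_median",
    "g1": 711579,
    "g2": 575000,
    "psa_fixed": false
  },
  {
    "name": "p_referral",
    "label": "Inconclusive result referred to biopsy",
    "base": 0.75,
    "low": 0,
    "high": 1,
    "family": "beta",
    "parameterization": "mean_sd",
    "g1": 0.75,
    "g2": 0.15,
    "psa_fixed": false
  },
  {
    "name": "sens_algo",
    "label": "Algorithm sensitivity",
    "base": 0.53,
    "low": 0.41,
    "high": 0.65,
    "family": "beta",
    "parameterization": "mean_sd",
    "g1": 0.53,
    "g2": 0.059,
    "psa_fixed": false
  },
  {
    "name": "spec_algo",
    "label": "Algorithm specificity",
    "base": 0.86,
    "low": 0.77,
    "high": 0.93,
    "family": "beta",
    "parameterization": "mean_sd",
    "g1": 0.86,
    "g2": 0.04,
    "psa_fixed": false
  },
  {
    "name": "sens_gc",
    "label": "Genomic classifier sensitivity",
    "base": 0.68,
    "low": 0.55,
    "high": 0.73,
    "family": "beta",
    "parameterization": "mean_sd",
    "g1": 0.68,
    "g2": 0.045,
    "psa_fixed": false
  },
  {
    "name": "spec_gc",
    "label": "Genomic classifier specificity",
    "base": 0.92,
    "low": 0.81,
    "high": 0.95,
    "family": "beta",
    "parameterization": "mean_sd",
    "g1": 0.92,
    "g2": 0.035,
    "psa_fixed": false
  },
  {
    "name": "p_biopsy_death",
    "label": "Biopsy results in death",
    "base": 0.064,
    "low": 0.01,
    "high": 0.17,
    "family": "beta",
    "parameterization": "mean_sd",
    "g1": 0.064,
    "g2": 0.02,
    "psa_fixed": false
  },
  {
    "name": "sens_biopsy",
    "label": "Biopsy sensitivity",
    "base": 0.75,
    "low": 0.5,
    "high": 1,
    "family": "beta",
    "parameterization": "shape_pair",
    "g1": 27,
    "g2": 7,
    "psa_fixed": false
  },
  {
    "name": "spec_biopsy",
    "label": "Biopsy specificity",
    "base": 0.9,
    "low": 0.8,
    "high": 1,
    "family": "beta",
    "parameterization": "mean_sd",
    "g1": 0.9,
    "g2": 0.05,
    "psa_fixed": false
  },
  {
    "name": "p_fp_benefit_test",
    "label": "FP treatment benefit (test/biopsy arms)",
    "base": 0,
    "low": 0,
    "high": 0.4,
    "family": "fixed",
    "parameterization": "point",
    "g1": 0,
    "g2": null,
    "psa_fixed": true
  },
  {
    "name": "p_fp_benefit_treatall",
    "label": "FP treatment benefit (treat-all arm)",
    "base": 0,
    "low": 0,
    "high": 0.2,
    "family": "fixed",
    "parameterization": "point",
    "g1": 0,
    "g2": null,
    "psa_fixed": true
  },
  {
    "name": "prevalence",
    "label": "IPF prevalence in work-up population",
    "base": 0.404,
    "low": 0.1,
    "high": 0.6,
    "family": "beta",
    "parameterization": "shape_pair",
    "g1": 626,
    "g2": 922,
    "psa_fixed": false
  },
  {
    "name": "u_biopsy",
    "label": "Disutility of surgical lung biopsy",
    "base": 0.013,
    "low": 0,
    "high": 0.026,
    "family": "fixed",
    "parameterization": "point",
    "g1": 0.013,
    "g2": null,
    "psa_fixed": true
  },
  {
    "name": "q_fn",
    "label": "Lifetime QALYs, false negative",
    "base": 3.78,
    "low": 2.78,
    "high": 4.78,
    "family": "lognormal",
    "parameterization": "mean_median",
    "g1": 3.78,
    "g2": 3.7,
    "psa_fixed": false
  },
  {
    "name": "q_fp",
    "label": "Lifetime QALYs, false positive",
    "base": 3.7,
    "low": 2.7,
    "high": 4.7,
    "family": "lognormal",
    "parameterization": "mean_median",
    "g1": 3.7,
    "g2": 3.6,
    "psa_fixed": false
  },
  {
    "name": "q_tn",
    "label": "Lifetime QALYs, true negative",
    "base": 3.78,
    "low": 2.85,
    "high": 4.85,
    "family": "lognormal",
    "parameterization": "mean_median",
    "g1": 3.78,
    "g2": 3.7,
    "psa_fixed": false
  },
  {
    "name": "q_tp",
    "label": "Lifetime QALYs, true positive",
    "base": 4.15,
    "low": 3.15,
    "high": 5.15,
    "family": "lognormal",
    "parameterization": "mean_median",
    "g1": 4.15,
    "g2": 4.05,
    "psa_fixed": false
  },
  {
    "name": "u_complication",
    "label": "Treatment-complication disutility",
    "base": 0.03,
    "low": 0,
    "high": 0.1,
    "family": "normal",
    "parameterization": "mean_sd",
    "g1": 0.03,
    "g2": 0.01,
    "psa_fixed": false
  }
]
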