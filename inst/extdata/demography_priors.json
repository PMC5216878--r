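{
  "_comment": "Reconstructed wide priors around literature-scale values for the common-bean demographic history; the original prior table is not public. Editable; all known-truth tests use fixed_priors() instead.",
  "model1": {
    "T_ANC":   {"dist": "logunif", "min": 50000, "max": 500000},
    "T_BMD":   {"dist": "unif", "min": 6000, "max": 10000},
    "T_EMD":   {"dist": "unif", "min": 3000, "max": 6000},
    "T_BAB":   {"dist": "unif", "min": 20000, "max": 40000},
    "T_EAB":   {"dist": "unif", "min": 15000, "max": 20000},
    "T_BAD":   {"dist": "unif", "min": 6000, "max": 10000},
    "T_EAD":   {"dist": "unif", "min": 3000, "max": 6000},
    "N_ANC":   {"dist": "logunif", "min": 50000, "max": 1000000},
    "N_MWANC": {"dist": "logunif", "min": 50000, "max": 1000000},
    "N_AWANC": {"dist": "logunif", "min": 20000, "max": 500000},
    "N_BA":    {"dist": "logunif", "min": 1000, "max": 50000},
    "N_MW":    {"dist": "logunif", "min": 50000, "max": 1000000},
    "N_MD":    {"dist": "logunif", "min": 10000, "max": 500000},
    "N_AW":    {"dist": "logunif", "min": 20000, "max": 500000},
    "N_AD":    {"dist": "logunif", "min": 10000, "max": 300000},
    "I_MD":    {"dist": "logunif", "min": 0.1, "max": 10},
    "I_AD":    {"dist": "logunif", "min": 0.1, "max": 10},
    "M_WD":    {"dist": "unif", "min": 0, "max": 1e-05},
    "M_DW":    {"dist": "unif", "min": 0, "max": 1e-05},
    "M_MWAW":  {"dist": "unif", "min": 0, "max": 1e-06},
    "M_AWMW":  {"dist": "unif", "min": 0, "max": 1e-06}
  },
  "model2": {
    "T_ANC":   {"dist": "logunif", "min": 50000, "max": 500000},
    "T_BMD":   {"dist": "unif", "min": 6000, "max": 10000},
    "T_EMD":   {"dist": "unif", "min": 3000, "max": 6000},
    "T_BAD":   {"dist": "unif", "min": 6000, "max": 10000},
    "T_EAD":   {"dist": "unif", "min": 3000, "max": 6000},
    "N_ANC":   {"dist": "logunif", "min": 50000, "max": 1000000},
    "N_MWANC": {"dist": "logunif", "min": 50000, "max": 1000000},
    "N_AWANC": {"dist": "logunif", "min": 20000, "max": 500000},
    "N_BA":    {"dist": "logunif", "min": 1000, "max": 50000},
    "N_MW":    {"dist": "logunif", "min": 100000, "max": 2000000},
    "N_MD":    {"dist": "logunif", "min": 10000, "max": 500000},
    "N_AW":    {"dist": "logunif", "min": 50000, "max": 1000000},
    "N_AD":    {"dist": "logunif", "min": 10000, "max": 300000},
    "I_MD":    {"dist": "logunif", "min": 0.1, "max": 10},
    "I_AD":    {"dist": "logunif", "min": 0.1, "max": 10},
    "M_WD":    {"dist": "unif", "min": 0, "max": 1e-05},
    "M_DW":    {"dist": "unif", "min": 0, "max": 1e-05},
    "M_MWAW":  {"dist": "unif", "min": 0, "max": 1e-06},
    "M_AWMW":  {"dist": "unif", "min": 0, "max": 1e-06}
  }
}
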