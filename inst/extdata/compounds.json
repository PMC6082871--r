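[
  {
    "name": "Cys-ME",
    "pKa": 7,
    "dG0_kcal_mol": 7.3,
    "dG0_homodimer_kcal_mol": -1.2,
    "dx_A": 0.35,
    "dG_barrier_kT": 13.797416,
    "total_concentration_M": 0.00263245553203,
    "pH": 7.5,
    "s_charge_e": -0.738
  },
  {
    "name": "penicillamine",
    "pKa": 7.9,
    "dG0_kcal_mol": 1,
    "dG0_homodimer_kcal_mol": -1,
    "dx_A": 0.35,
    "dG_barrier_kT": 13.425852,
    "total_concentration_M": 0.00702377286302,
    "pH": 7.5,
    "s_charge_e": -0.755
  },
  {
    "name": "L-cysteine",
    "pKa": 8.3,
    "dG0_kcal_mol": 0,
    "dG0_homodimer_kcal_mol": 0,
    "dx_A": 0.35,
    "dG_barrier_kT": 11.972866,
    "total_concentration_M": 0.0146191468896,
    "pH": 7.5,
    "s_charge_e": -0.821
  },
  {
    "name": "NAC",
    "pKa": 9.5,
    "dG0_kcal_mol": -9.6,
    "dG0_homodimer_kcal_mol": -2,
    "dx_A": 0.35,
    "dG_barrier_kT": 10.6,
    "total_concentration_M": 0.0202,
    "pH": 7.5,
    "s_charge_e": -0.882
  },
  {
    "name": "glutathione",
    "pKa": 8.8,
    "dG0_kcal_mol": -3.5,
    "dG0_homodimer_kcal_mol": -1.5,
    "dx_A": 0.35,
    "dG_barrier_kT": 11.7,
    "total_concentration_M": 0.0104763115748,
    "pH": 7.5,
    "s_charge_e": -0.833
  },
  {
    "name": "mesna",
    "pKa": 9.1,
    "dG0_kcal_mol": -6.7,
    "dG0_homodimer_kcal_mol": -1.8,
    "dx_A": 0.35,
    "dG_barrier_kT": 11.2,
    "total_concentration_M": 0.0408107170553,
    "pH": 7.5,
    "s_charge_e": -0.855
  },
  {
    "name": "thioglycerol",
    "pKa": 9.5,
    "dG0_kcal_mol": -4.5,
    "dG0_homodimer_kcal_mol": -1.4,
    "dx_A": 0.35,
    "dG_barrier_kT": 11.9,
    "total_concentration_M": 0.101,
    "pH": 7.5,
    "s_charge_e": -0.824
  },
  {
    "name": "NAC-ME",
    "pKa": 9.4,
    "dG0_kcal_mol": -2.5,
    "dG0_homodimer_kcal_mol": -1.6,
    "dx_A": 0.35,
    "dG_barrier_kT": 10.9,
    "total_concentration_M": 0.0804328234724,
    "pH": 7.5,
    "s_charge_e": -0.869
  },
  {
    "name": "1-mercapto-2-propanol",
    "pKa": 9.7,
    "dG0_kcal_mol": -3,
    "dG0_homodimer_kcal_mol": -1.3,
    "dx_A": 0.35,
    "dG_barrier_kT": 12.1,
    "total_concentration_M": 0.159489319246,
    "pH": 7.5,
    "s_charge_e": -0.815
  }
]
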