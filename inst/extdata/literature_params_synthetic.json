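{
  "description": "SYNTHETIC STAND-IN literature kinetic rate table. Units: forward rates kf1..kf4 in nM^-1 s^-1, reverse rates kr1..kr4 in s^-1. The soluble receptor-antibody arm (kf1/kr1) is common to all pairs and emulates a tight tag-receptor bond (KD1 0.1 nM, off-rate 2e-4 s^-1). The antibody-antigen arm (kf2/kr2, repeated as kf3/kr3 for the receptor-bound antibody) uses published SPR kinetics typical of each antibody: FMC63/CD19 KD ~1.5 nM, Rituximab/CD20 KD ~8 nM, Herceptin/HER2 KD ~0.5 nM, Cetuximab/EGFR KD ~0.4 nM. The direct capture of a T cell receptor by an antibody already anchored on a tumor cell (kf4/kr4) is encounter-limited and sterically constrained, so its on-rate is set 100x below the soluble arm (kf4 2e-5, KD4 10 nM); with this route weak, ternary formation runs through the antibody-armed T cell, making it sensitive to the receptor-antibody on-rate, as the adaptor-receptor system is reported to be. These are NOT the study's tabulated values, which are not reproduced in its main text.",
  "pairs": {
    "FMC63_synNotch": {
      "kf1": 2e-3, "kf2": 2.2e-4, "kf3": 2.2e-4, "kf4": 2e-5,
      "kr1": 2e-4, "kr2": 3.3e-4, "kr3": 3.3e-4, "kr4": 2e-4,
      "metadata": {"antibody": "FMC63", "antigen": "CD19", "receptor": "synNotch", "source": "synthetic stand-in"}
    },
    "Rituximab_synNotch": {
      "kf1": 2e-3, "kf2": 5e-5, "kf3": 5e-5, "kf4": 2e-5,
      "kr1": 2e-4, "kr2": 4e-4, "kr3": 4e-4, "kr4": 2e-4,
      "metadata": {"antibody": "Rituximab", "antigen": "CD20", "receptor": "synNotch", "source": "synthetic stand-in"}
    },
    "Herceptin_synNotch": {
      "kf1": 2e-3, "kf2": 7.1e-4, "kf3": 7.1e-4, "kf4": 2e-5,
      "kr1": 2e-4, "kr2": 3.6e-4, "kr3": 3.6e-4, "kr4": 2e-4,
      "metadata": {"antibody": "Herceptin", "antigen": "HER2", "receptor": "synNotch", "source": "synthetic stand-in"}
    },
    "Cetuximab_synNotch": {
      "kf1": 2e-3, "kf2": 2.1e-4, "kf3": 2.1e-4, "kf4": 2e-5,
      "kr1": 2e-4, "kr2": 8.2e-5, "kr3": 8.2e-5, "kr4": 2e-4,
      "metadata": {"antibody": "Cetuximab", "antigen": "EGFR", "receptor": "synNotch", "source": "synthetic stand-in"}
    },
    "FMC63_CAR": {
      "kf1": 2e-3, "kf2": 2.2e-4, "kf3": 2.2e-4, "kf4": 2e-5,
      "kr1": 2e-4, "kr2": 3.3e-4, "kr3": 3.3e-4, "kr4": 2e-4,
      "metadata": {"antibody": "FMC63", "antigen": "CD19", "receptor": "CAR", "source": "synthetic stand-in"}
    },
    "Rituximab_CAR": {
      "kf1": 2e-3, "kf2": 5e-5, "kf3": 5e-5, "kf4": 2e-5,
      "kr1": 2e-4, "kr2": 4e-4, "kr3": 4e-4, "kr4": 2e-4,
      "metadata": {"antibody": "Rituximab", "antigen": "CD20", "receptor": "CAR", "source": "synthetic stand-in"}
    },
    "Herceptin_CAR": {
      "kf1": 2e-3, "kf2": 7.1e-4, "kf3": 7.1e-4, "kf4": 2e-5,
      "kr1": 2e-4, "kr2": 3.6e-4, "kr3": 3.6e-4, "kr4": 2e-4,
      "metadata": {"antibody": "Herceptin", "antigen": "HER2", "receptor": "CAR", "source": "synthetic stand-in"}
    },
    "Cetuximab_CAR": {
      "kf1": 2e-3, "kf2": 2.1e-4, "kf3": 2.1e-4, "kf4": 2e-5,
      "kr1": 2e-4, "kr2": 8.2e-5, "kr3": 8.2e-5, "kr4": 2e-4,
      "metadata": {"antibody": "Cetuximab", "antigen": "EGFR", "receptor": "CAR", "source": "synthetic stand-in"}
    }
  }
}
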