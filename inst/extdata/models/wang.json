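{
  "name": "wang",
  "description": "Five-state linear-chain Markov model of IKr (hERG): C1 <-> C2 <-> C3 <-> O <-> I. The C2 <-> C3 step is voltage independent. 14 kinetic parameters plus the maximal conductance (15 parameters in total).",
  "provenance": "Rate structure and kinetic parameter values transcribed from Wang, Rasmusson et al. (1997), J Physiol 502(1):45-60, using the parameter set obtained with the 2 mM KCl extracellular solution (frog oocytes over-expressing hERG, room temperature). Wang et al. report no whole-cell maximal conductance in uS for this setting; the packaged g = 0.1524 uS is a synthetic-study choice matching the scale of the packaged four-state model so that simulated currents are comparable. Units: ms^-1 (a), mV^-1 (b), uS (g).",
  "states": ["C1", "C2", "C3", "O", "I"],
  "conducting_state": "O",
  "theta_f": {
    "aa0_a": 0.022348,
    "aa0_b": 0.01176,
    "ba0_a": 0.047002,
    "ba0_b": 0.0631,
    "kf":    0.023761,
    "kb":    0.036778,
    "aa1_a": 0.013733,
    "aa1_b": 0.038198,
    "ba1_a": 6.89e-5,
    "ba1_b": 0.04178,
    "ai_a":  0.090821,
    "ai_b":  0.023391,
    "bi_a":  0.006497,
    "bi_b":  0.03268
  },
  "g": 0.1524,
  "transitions": [
    {"from": "C1", "to": "C2", "kind": "exp_increasing", "a": "aa0_a", "b": "aa0_b"},
    {"from": "C2", "to": "C1", "kind": "exp_decreasing", "a": "ba0_a", "b": "ba0_b"},
    {"from": "C2", "to": "C3", "kind": "constant",       "a": "kf"},
    {"from": "C3", "to": "C2", "kind": "constant",       "a": "kb"},
    {"from": "C3", "to": "O",  "kind": "exp_increasing", "a": "aa1_a", "b": "aa1_b"},
    {"from": "O",  "to": "C3", "kind": "exp_decreasing", "a": "ba1_a", "b": "ba1_b"},
    {"from": "O",  "to": "I",  "kind": "exp_increasing", "a": "ai_a",  "b": "ai_b"},
    {"from": "I",  "to": "O",  "kind": "exp_decreasing", "a": "bi_a",  "b": "bi_b"}
  ]
}
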