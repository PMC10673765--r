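{
  "name": "beattie",
  "description": "Four-state Markov model of IKr (hERG): closed (C), open (O), inactivated (I) and inactivated-closed (IC) states arranged in a cycle. Activation (C->O, IC->I) and inactivation (O->I, C->IC) each use one exponential rate pair, giving 8 kinetic parameters plus the maximal conductance.",
  "provenance": "Rate structure and parameter values transcribed from Beattie et al. (2018), J Physiol 596(10):1813-1828, doi:10.1113/JP275733, cell #5 estimates obtained with the sinusoidal protocol on CHO cells over-expressing hERG1a at room temperature. Units: ms^-1 (a), mV^-1 (b), uS (g).",
  "states": ["C", "O", "I", "IC"],
  "conducting_state": "O",
  "theta_f": {
    "p1": 2.26e-4,
    "p2": 0.0699,
    "p3": 3.45e-5,
    "p4": 0.05462,
    "p5": 0.0873,
    "p6": 8.91e-3,
    "p7": 5.15e-3,
    "p8": 0.03158
  },
  "g": 0.1524,
  "transitions": [
    {"from": "C",  "to": "O",  "kind": "exp_increasing", "a": "p1", "b": "p2"},
    {"from": "O",  "to": "C",  "kind": "exp_decreasing", "a": "p3", "b": "p4"},
    {"from": "IC", "to": "I",  "kind": "exp_increasing", "a": "p1", "b": "p2"},
    {"from": "I",  "to": "IC", "kind": "exp_decreasing", "a": "p3", "b": "p4"},
    {"from": "O",  "to": "I",  "kind": "exp_increasing", "a": "p5", "b": "p6"},
    {"from": "I",  "to": "O",  "kind": "exp_decreasing", "a": "p7", "b": "p8"},
    {"from": "C",  "to": "IC", "kind": "exp_increasing", "a": "p5", "b": "p6"},
    {"from": "IC", "to": "C",  "kind": "exp_decreasing", "a": "p7", "b": "p8"}
  ]
}
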