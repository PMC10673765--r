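# name: d0-like
# v_hold: -80
# sample_rate: 10
duration_ms,v_start_mV,v_end_mV
400,-80,-80
200,-120,-120
600,-120,-80
800,-80,-80
40,-80,40
600,40,-85
80,-85,-80
600,-80,-80
40,-80,40
1000,40,-85
80,-85,-80
600,-80,-80
40,-80,40
1400,40,-85
80,-85,-80
600,-80,-80
40,-80,40
800,40,-85
80,-85,-80
600,-80,-80
200,-120,-120
600,-120,-80
400,-80,-80
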