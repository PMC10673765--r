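# name: d5-like
# v_hold: -80
# sample_rate: 10
duration_ms,v_start_mV,v_end_mV
400,-80,-80
200,-120,-120
600,-120,-80
800,-80,-80
600,-110,-110
1600,50,50
1800,-55,-55
1200,10,10
600,-120,-120
1200,60,60
600,-85,-85
1200,30,30
200,-120,-120
600,-120,-80
400,-80,-80
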