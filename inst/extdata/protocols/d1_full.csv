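# name: d1-like
# v_hold: -80
# sample_rate: 10
duration_ms,v_start_mV,v_end_mV
400,-80,-80
200,-120,-120
600,-120,-80
800,-80,-80
1400,40,40
1600,-50,-50
1000,20,20
1200,-80,-80
1000,60,60
600,-120,-120
1400,0,0
600,-100,-100
200,-120,-120
600,-120,-80
400,-80,-80
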