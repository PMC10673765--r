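# name: d2-like
# v_hold: -80
# sample_rate: 10
duration_ms,v_start_mV,v_end_mV
400,-80,-80
200,-120,-120
600,-120,-80
800,-80,-80
1400,60,60
1800,-50,-50
1200,40,40
400,-100,-100
1200,20,20
560,-120,-120
1440,0,0
800,-60,-60
200,-120,-120
600,-120,-80
400,-80,-80
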