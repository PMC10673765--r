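# name: d3-like
# v_hold: -80
# sample_rate: 10
duration_ms,v_start_mV,v_end_mV
400,-80,-80
200,-120,-120
600,-120,-80
800,-80,-80
1800,0,0
1600,-60,-60
1200,60,60
400,-90,-90
1200,-20,-20
600,-110,-110
1200,40,40
800,-50,-50
200,-120,-120
600,-120,-80
400,-80,-80
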