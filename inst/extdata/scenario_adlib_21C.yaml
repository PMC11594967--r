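# Abundant-food reference scenario.
T_celsius: 21
f_mode: constant
f_value: 1
sex: female
horizon_days: 200
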