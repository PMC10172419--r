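sex,age,coefficient_per_msv
F,29,0.0138059701493
F,67,0.00378630705394
F,70,0.00343634686347
F,81,0.0023532388664
M,19,0.0118611878453
M,51,0.00492491166078
M,63,0.00354241877256
M,76,0.00246803977273
M,77,0.00241847826087
M,79,0.0022896039604
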