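"element","mass_fraction","sd"
"Ca",0.0302586210693144,0.00155045
"Mg",0.0702364470746579,0.0035332
"Ti",0.0113480478134843,0.00042
"P",7e-04,0
"K",0.0092,0
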