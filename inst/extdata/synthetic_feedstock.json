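{"name":"synthetic metabasalt","element_mass_fraction":{"Ca":0.031009,"Mg":0.070664,"Ti":0.010899,"P":0.0007,"K":0.0092},"sd":{"Ti":0.00042,"Ca":0.00155045,"Mg":0.0035332},"p80_um":267}
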