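# Reference tolerances for the illustrative fixture.  The ethephon value
# is the published lowest U.S. EPA food-commodity tolerance (eggs); the
# remaining rows are synthetic.
pesticide,lowest_tolerance_ppm,commodity
ethephon,0.002,eggs
azoxystrobin,0.01,synthetic
dimethomorph,0.05,synthetic
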