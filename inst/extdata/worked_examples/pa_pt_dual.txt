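These experiments confirm projections from Pa, Pt, and other midline nuclei to the amygdala.
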