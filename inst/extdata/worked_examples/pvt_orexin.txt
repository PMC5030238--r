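The paraventricular thalamus (PVT), a midline thalamic nucleus, receives dense innervations from lateral hypothalamic orexin neurons and is involved in the regulation of cognition.
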