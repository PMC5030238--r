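nsubj(innervate-22, neurons-20)
nn(neurons-20, PVT-19)
nsubj(activates-18, stress-17)
dobj(activates-18, neurons-20)
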