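nsubj(receives-13, thalamus-3)
det(thalamus-3, The-1)
nn(thalamus-3, paraventricular-2)
dobj(receives-13, innervations-15)
amod(innervations-15, dense-14)
prep_from(receives-13, neurons-20)
amod(neurons-20, lateral-17)
amod(neurons-20, hypothalamic-18)
nn(neurons-20, orexin-19)
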