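nsubjpass(innervated-11, aPVT-8)
det(aPVT-8, the-7)
agent(innervated-11, subiculum-15)
det(subiculum-15, the-13)
amod(subiculum-15, ventral-14)
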