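nsubj(projects-17, subnucleus-16)
det(subnucleus-16, the-12)
amod(subnucleus-16, external-13)
amod(subnucleus-16, lateral-14)
nn(subnucleus-16, parabrachial-15)
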