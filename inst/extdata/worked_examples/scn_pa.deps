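xsubj(project-8, nucleus-3)
det(nucleus-3, The-1)
amod(nucleus-3, suprachiasmatic-2)
prep_to(project-8, Pa-11)
prep_in(Pa-11, rats-13)
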