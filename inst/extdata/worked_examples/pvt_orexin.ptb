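(S (NP (NP (DT The) (JJ paraventricular) (NN thalamus)) (PRN (-LRB- -LRB-) (NP (NN PVT)) (-RRB- -RRB-)) (, ,) (NP (DT a) (JJ midline) (JJ thalamic) (NN nucleus)) (, ,)) (VP (VP (VBZ receives) (NP (JJ dense) (NNS innervations)) (PP (IN from) (NP (JJ lateral) (JJ hypothalamic) (NN orexin) (NNS neurons)))) (CC and) (VP (VBZ is) (VBN involved) (PP (IN in) (NP (NP (DT the) (NN regulation)) (PP (IN of) (NP (NN cognition))))))) (. .))
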