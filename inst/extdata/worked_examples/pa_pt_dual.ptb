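(S (NP (DT These) (NNS experiments)) (VP (VBP confirm) (NP (NP (NNS projections)) (PP (IN from) (NP (NP (NNP Pa)) (, ,) (NP (NNP Pt)) (, ,) (CC and) (NP (JJ other) (JJ midline) (NNS nuclei)))) (PP (TO to) (NP (DT the) (NN amygdala))))) (. .))
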