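(S (NP (DT The) (JJ suprachiasmatic) (NN nucleus)) (VP (VBZ is) (ADVP (RB well)) (VBN known) (S (VP (TO to) (VP (VB project) (ADVP (RB densely)) (PP (TO to) (NP (NP (NNP Pa)) (PP (IN in) (NP (NNS rats))))))))) (. .))
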