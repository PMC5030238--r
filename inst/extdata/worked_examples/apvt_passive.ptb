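(S (PP (IN In) (NP (NN addition))) (, ,) (NP (PRP we)) (VP (VBD found) (SBAR (IN that) (S (NP (DT the) (NN aPVT)) (VP (VP (VBD was) (ADVP (RB strongly)) (VP (VBN innervated) (PP (IN by) (NP (DT the) (JJ ventral) (NN subiculum))))) (CC but) (S (NP (DT this) (NN projection)) (VP (ADVP (RB largely)) (VBD did) (RB not) (VP (VB involve) (NP (DT the) (NN pPVT))))))))) (. .))
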