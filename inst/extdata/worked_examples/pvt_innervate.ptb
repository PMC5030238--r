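(S (ADVP (RB However)) (, ,) (NP (PRP it)) (VP (VBZ appears) (ADJP (JJ likely)) (SBAR (IN that) (S (NP (EX there)) (VP (VBP are) (NP (NP (DT no) (JJ substantial) (NNS differences)) (PP (IN in) (NP (NP (DT the) (NN degree)) (SBAR (WHPP (TO to) (WHNP (WDT which))) (S (NP (NN stress)) (VP (VBZ activates) (NP (NP (NN PVT) (NNS neurons)) (SBAR (WHNP (WDT that)) (S (VP (VB innervate) (NP (DT the) (NN PFC) (, ,) (NN NAS) (CC and) (NN AMG)))))))))))))))) (. .))
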