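(S (NP (NP (DT An) (JJ anterograde) (NN tracer) (NN injection)) (PP (IN into) (NP (DT the) (JJ dorsal) (JJ midline) (NN thalamus)))) (VP (VBD revealed) (NP (NP (JJ strong) (NNS projections)) (PP (TO to) (NP (NP (DT the) (NN accumbens) (NN nucleus)) (, ,) (NP (JJ basal) (NN amygdala)) (, ,) (NP (JJ lateral) (NN septum)) (, ,) (CC and) (NP (NN hypothalamus)))))) (. .))
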