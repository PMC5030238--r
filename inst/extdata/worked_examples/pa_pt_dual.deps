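nsubj(confirm-3, experiments-2)
det(experiments-2, These-1)
dobj(confirm-3, projections-4)
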