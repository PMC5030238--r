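dobj(revealed-10, projections-12)
nsubj(revealed-10, injection-4)
amod(injection-4, anterograde-2)
nn(injection-4, tracer-3)
prep_into(injection-4, thalamus-9)
amod(thalamus-9, dorsal-7)
amod(thalamus-9, midline-8)
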