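vmod(neurons-30, projecting-31)
nn(neurons-30, orexin-29)
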