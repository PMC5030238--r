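The suprachiasmatic nucleus is well known to project densely to Pa in rats.
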