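In addition, we found that the aPVT was strongly innervated by the ventral subiculum but this projection largely did not involve the pPVT.
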