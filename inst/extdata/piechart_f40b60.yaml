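label: f40b60
transmission: 0
filtering: 0.4
reflection: 0
blockage: 0.6
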