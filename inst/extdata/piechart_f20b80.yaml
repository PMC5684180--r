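label: f20b80
transmission: 0
filtering: 0.2
reflection: 0
blockage: 0.8
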