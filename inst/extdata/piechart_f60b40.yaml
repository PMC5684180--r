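# FAS regime mixture among injured neurons: 60% filtering, 40% blockage
label: f60b40
transmission: 0
filtering: 0.6
reflection: 0
blockage: 0.4
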