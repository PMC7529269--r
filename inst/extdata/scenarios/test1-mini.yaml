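# Ischemic slab, desk scale (32x32, Nt = 200, 9 train / 4 test instances)
builder: test1-mini
args: {}
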