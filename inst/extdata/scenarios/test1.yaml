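# Ischemic slab, full scale (64x64, Nt = 1000, 49 train / 36 test instances)
builder: test1
args: {}
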