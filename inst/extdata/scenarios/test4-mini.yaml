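# Restitution variability, desk scale (32x32, Nt = 200)
builder: test4
args:
  nx: 32
  Nt: 200
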