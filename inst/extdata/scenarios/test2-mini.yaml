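# S1-S2 re-entry, desk scale (64x64, Nt = 80)
builder: test2
args:
  variant: reentry_only
  nx: 64
  Nt: 80
  n_train: 5
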