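# S1-S2 re-entry, parameter box [0.5, 1.1] cm (re-entry and non-re-entry)
builder: test2
args:
  variant: full
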