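# S1-S2 re-entry, parameter box [0.8, 1.1] cm (re-entrant dynamics only)
builder: test2
args:
  variant: reentry_only
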