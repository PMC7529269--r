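# Restitution variability (conductivities + APD parameter), full scale
builder: test4
args: {}
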