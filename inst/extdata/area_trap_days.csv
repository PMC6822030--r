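area,trap_days
jura,19035
vosges,6804
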