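label,n_events
feeding,200
no_feeding,351
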