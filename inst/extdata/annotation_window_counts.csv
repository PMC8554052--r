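window,n_events
ZT00-01,202
ZT04-05,189
ZT07-08,213
ZT10-11,242
ZT12-13,339
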