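component,percent
juice,9.189
dahi,60
water,15.311
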