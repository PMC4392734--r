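# candidate genes altered in the worked example (daf-2 is not listed: it is the linker)
daf-16
daf-3
peb-1
myo-2
daf-36
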