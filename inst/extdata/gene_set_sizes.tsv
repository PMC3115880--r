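set_label	size
gc_induced	696
gc_repressed	477
lf_induced	596
lf_repressed	441
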