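PERM12_PATH	two-gene toy pathway on the 12-vertex fixture	V08	V09
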