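STAR_SEED	toy seed set: two leaves of the K1,3 star	l1	l2
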