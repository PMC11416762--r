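protein1 protein2 combined_score
P1 P2 150
P2 P3 700
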