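>peptidase_a17_synthetic Synthetic retroviral-protease-like tag (synthetic 60-aa tag)
VLTWSVGPALAWESLWGMAIANYYTVCSCYQNNNTMKPNAWRWLREQAVRRYDFRVQYPA
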