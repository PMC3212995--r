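>rve_synthetic Synthetic integrase-core-like tag (synthetic 60-aa tag)
KLQCEFNEEVWCWIHTRPDFCNFQSQRPKLWVTVYCQLVGFPAWAWCLISGGISYADRMK
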