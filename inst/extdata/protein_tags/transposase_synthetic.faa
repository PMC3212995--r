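>transposase_synthetic Synthetic DDE-transposase-like tag (synthetic 60-aa tag)
FCHFDDKPKLMFQGCHYREADVANPWTAEPYWCCPQTWGEYASYAKNTGDTYARAYGAMA
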