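>rvt_1_synthetic Synthetic reverse-transcriptase-like tag, non-LTR lineage (synthetic 60-aa tag)
ISMEDDSPNELDGRLKAFNVYHATFTDLHYQEQECYCPCFKYMAGSFWFFEHCCGYTDCY
>rvt_2_synthetic Synthetic reverse-transcriptase-like tag, LTR lineage (synthetic 60-aa tag)
RDRCLDHRWVEATHISSKHGNWFDEMRPMYRDSAEQSQMPPVWIQVGERNRFDNYWCLPC
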