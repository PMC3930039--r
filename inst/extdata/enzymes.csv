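name,recognition,cut_offset
TaqI,TCGA,1
NdeII,GATC,0
MseI,TTAA,1
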