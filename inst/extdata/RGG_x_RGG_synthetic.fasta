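>RGG_x_RGG_synthetic TEV-cleavable tandem RGG construct (synthetic stand-in sequence; RGG-like low-complexity composition; TEV fragments 17843/17907 Da average mass)
MGSRGGYGGDRGGDYGGRGGSMGGRGGYDDRGGSGRGGYGGDRGGDYGGRGGSMGGRGGY
DDRGGSGRGGYGGDRGGDYGGRGGSMGGRGGYDDRGGSGRGGYGGDRGGDYGGRGGSMGG
RGGYDDRGGSGRGGYGGDRGGDYGGRGGSMGGRGGYDDRGGSGGGGGGGGGGGGGGAASS
SSSSSSGSENLYFQGASRGGYGGDRGGDYGGRGGSMGGRGGYDDRGGSGRGGYGGDRGGD
YGGRGGSMGGRGGYDDRGGSGRGGYGGDRGGDYGGRGGSMGGRGGYDDRGGSGRGGYGGD
RGGDYGGRGGSMGGRGGYDNRGGSGRGGYGGDRGGNYGGRGGSMGGRGGYDNRGGSGGGG
GGGGGGGGGGGGGGGGSSSSSSSSSGRGGYSGGS
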