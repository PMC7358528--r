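>parent_synthetic 37-residue CS-alpha/beta stand-in (NOT the real toxin sequence); Q12/K15/K18/K26/D33, Cys at 7,13,17,28,32,34
GVEINVCSGSPQCIKPCKDAGMRFGKMCNRKCDCTPK
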