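>t1 synthetic example target
ACGTACGTTGACCAGT
>t2 synthetic example target
ACGTACGATGACCAGT
>t3 synthetic example target
GGGTTTACGT
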