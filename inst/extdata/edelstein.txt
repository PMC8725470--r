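# Edelstein autocatalytic network (reduced form)
# species: A (autocatalytic), B (binding partner), C (complex)
A -> 2A
2A -> A
A + B -> C
C -> A + B
C -> B
B -> C
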