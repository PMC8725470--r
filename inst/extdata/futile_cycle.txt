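# Futile signaling cycle with a two-state kinase (E1/E2).
# S: substrate, Sstar: phosphorylated substrate, E1S/E2S: enzyme:substrate
# complexes.  Biterminal C-graph.
@species: S E1 E1S Sstar E2 E2S
S + E1 -> E1S
E1S -> S + E1
E1S -> E1 + Sstar
S + E2 -> E2S
E2S -> S + E2
E2S -> E2 + Sstar
Sstar -> S
E1 -> E2
E2 -> E1
E1S -> E2S
E2S -> E1S
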