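# Prion-like conformation conversion between two kinase states (E1, E2)
# coupled to two-step substrate phosphorylation by the active form E2.
# Biterminal C-graph (release of 2E1 / 2E2 from the conversion complexes).
@species: E1 E2 E1E2 E2E1 S Sstar SE2 Sstarstar SstarE2
E1E2 -> E1 + E2
E1 + E2 -> E1E2
E1 + E2 -> E2E1
E2E1 -> E1 + E2
E1E2 -> 2E1
E2E1 -> 2E2
S + E2 -> SE2
SE2 -> S + E2
SE2 -> Sstar + E2
Sstar + E2 -> SstarE2
SstarE2 -> Sstar + E2
SstarE2 -> Sstarstar + E2
Sstarstar -> Sstar
Sstar -> S
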