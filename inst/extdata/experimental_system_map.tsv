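source	mapped
Affinity Capture-MS	affinity-capture-MS
Affinity Capture-Western	affinity-capture-immunoblot
Affinity Capture-Luminescence	affinity-capture-immunoblot
Two-hybrid	yeast-two-hybrid
Yeast Two-hybrid	yeast-two-hybrid
FRET	resonance-energy-transfer
BRET	resonance-energy-transfer
Kinase Activity	kinase-activity
Phosphatase Activity	phosphatase-activity
Reconstituted Complex	crystal-structure-reconstituted-complex
Co-crystal Structure	crystal-structure-reconstituted-complex
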