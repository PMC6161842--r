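# Built-in high-level category set: a reconstruction over generic
# GO-slim-level terms, curated for this package. It is DATA, not code:
# replace it with your own file for serious use. Member terms of one
# category must be mutual siblings in the GO graph (no ancestor/descendant
# pairs); load_categories() re-validates this against the ontology in use.
category	term
Cell cycle	GO:0007049
Cell cycle	GO:0051301
Cell cycle	GO:0007059
Cytoskeleton, cell adhesion, and polarity	GO:0007155
Cytoskeleton, cell adhesion, and polarity	GO:0005856
Cytoskeleton, cell adhesion, and polarity	GO:0007163
Differentiation	GO:0030154
Differentiation	GO:0009653
Growth	GO:0040007
Immune	GO:0002376
Metabolism	GO:0008152
Metabolism	GO:0003824
Reproduction	GO:0000003
Signalling pathways	GO:0007165
Signalling pathways	GO:0030545
Stem cell	GO:0019827
Stem cell	GO:0017145
Stimulus	GO:0050896
Trafficking and transport	GO:0006810
Trafficking and transport	GO:0005215
Transcription factors and regulators	GO:0003700
Transcription factors and regulators	GO:0006355
Translation	GO:0006412
Translation	GO:0003735
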