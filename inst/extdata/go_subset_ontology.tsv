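term	parent	name
GO:0005575		cellular_component
GO:0005576	GO:0005575	extracellular region
GO:0005615	GO:0005576	extracellular space
GO:0071944	GO:0005575	cell periphery
GO:0005886	GO:0071944	plasma membrane
GO:0009986	GO:0071944	cell surface
GO:0008150		biological_process
GO:0007155	GO:0008150	cell adhesion
GO:0030198	GO:0008150	extracellular matrix organization
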