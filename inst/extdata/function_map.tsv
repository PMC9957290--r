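pfam_acc	family_name	broad_function	ig_like
pfam11999	DUF3494	IBP	FALSE
pfam16130	DUF4842	β-barrel Ig fold	TRUE
pfam07589	PEP C-term motif	Sorting/Exopolysaccharides	FALSE
pfam01345	DUF11	Cell wall-related	FALSE
pfam02010	REJ domain	Membrane associated	FALSE
pfam04519	Polymer-forming cytoskeletal	Cytoskeleton	FALSE
pfam13517	FG-GAP-like repeat	Cell adhesion	FALSE
pfam07593	ASPIC and UnbV	Cell adhesion	FALSE
pfam03797	Autotransporter β-domain	Secretion	FALSE
pfam13205	BIg-like domain	Tethering	TRUE
pfam02412	Thrombospondin type 3 repeat	Cell adhesion	FALSE
pfam01391	Collagen triple helix repeat	Cell adhesion	FALSE
pfam07603	DUF1566	Unknown	FALSE
pfam02494	HYR domain	Cell adhesion	FALSE
pfam14341	PilX N-terminal	Cell adhesion	FALSE
pfam04862	DUF642	Unknown (thought to be exclusive to plants)	FALSE
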