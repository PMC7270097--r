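# Simplified nearest-neighbour folding parameters for RNA (kcal/mol).
# Stack energies are keyed by the two base-pair types only (GC-type, AU-type,
# GU-type), i.e. orientation is averaged out; loop penalties are by total
# unpaired size. Magnitudes follow the familiar Turner-style parameter sets
# but are deliberately coarse: this table supports ordinal comparisons of
# folding potential, not literal reproduction of any published per-structure
# free energy. Sizes beyond the largest tabulated entry are extrapolated
# logarithmically in the loader (+ lxc * ln(size/max_tabulated)).
type	key1	key2	value
stack	GC	GC	-3.0
stack	GC	AU	-2.2
stack	GC	GU	-1.5
stack	AU	AU	-1.1
stack	AU	GU	-0.8
stack	GU	GU	-0.5
hairpin	3	.	5.4
hairpin	4	.	5.6
hairpin	5	.	5.7
hairpin	6	.	5.8
hairpin	7	.	5.9
hairpin	8	.	6.0
hairpin	9	.	6.1
hairpin	10	.	6.3
bulge	1	.	3.8
bulge	2	.	2.8
bulge	3	.	3.2
bulge	4	.	3.6
bulge	5	.	4.0
bulge	6	.	4.4
bulge	7	.	4.6
bulge	8	.	4.7
bulge	9	.	4.8
bulge	10	.	4.9
internal	2	.	4.1
internal	3	.	3.5
internal	4	.	1.7
internal	5	.	2.0
internal	6	.	2.1
internal	7	.	2.3
internal	8	.	2.5
internal	9	.	2.6
internal	10	.	2.8
multibranch	a	.	3.4
multibranch	b	.	0.4
multibranch	c	.	0.0
lxc	.	.	1.08
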