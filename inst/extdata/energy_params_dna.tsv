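# Simplified nearest-neighbour folding parameters for DNA hairpin folding
# (kcal/mol). Same layout and simplifications as energy_params_rna.tsv;
# stack magnitudes are weaker (SantaLucia-style order of magnitude) and the
# G.T wobble is only marginally stabilizing.
type	key1	key2	value
stack	GC	GC	-2.1
stack	GC	AU	-1.4
stack	GC	GU	-0.6
stack	AU	AU	-1.0
stack	AU	GU	-0.4
stack	GU	GU	-0.2
hairpin	3	.	3.5
hairpin	4	.	3.6
hairpin	5	.	3.7
hairpin	6	.	3.8
hairpin	7	.	3.9
hairpin	8	.	4.0
hairpin	9	.	4.1
hairpin	10	.	4.2
bulge	1	.	3.6
bulge	2	.	2.9
bulge	3	.	3.1
bulge	4	.	3.3
bulge	5	.	3.5
bulge	6	.	3.7
bulge	7	.	3.8
bulge	8	.	3.9
bulge	9	.	4.0
bulge	10	.	4.1
internal	2	.	3.9
internal	3	.	3.4
internal	4	.	1.9
internal	5	.	2.1
internal	6	.	2.2
internal	7	.	2.4
internal	8	.	2.5
internal	9	.	2.7
internal	10	.	2.8
multibranch	a	.	3.2
multibranch	b	.	0.4
multibranch	c	.	0.0
lxc	.	.	1.08
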