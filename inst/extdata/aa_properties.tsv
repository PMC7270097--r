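# Curated amino-acid physicochemical property table (31 scales).
# One row per amino acid (one-letter code), one column per property.
# Column provenance (values as commonly tabulated, e.g. in AAindex):
#   hydropathy               Kyte & Doolittle (1982) J Mol Biol 157:105
#   polarity                 Grantham (1974) Science 185:862
#   composition              Grantham (1974)
#   molecular_volume         Grantham (1974)
#   molecular_weight         free amino-acid molecular weight (g/mol)
#   isoelectric_point        standard free amino-acid pI values
#   bulkiness                Zimmerman, Eliezer & Simha (1968) J Theor Biol 21:170
#   polarity_zimmerman       Zimmerman et al. (1968)
#   helix_propensity_cf      Chou & Fasman (1978) P(alpha)
#   sheet_propensity_cf      Chou & Fasman (1978) P(beta)
#   turn_propensity_cf       Chou & Fasman (1978) P(turn)
#   residue_volume           Zamyatnin (1972) Prog Biophys Mol Biol 24:107
#   accessible_surface_area  Chothia (1976) tripeptide ASA (A^2)
#   hydrophilicity           Hopp & Woods (1981) PNAS 78:3824
#   flexibility              Bhaskaran & Ponnuswamy (1988) average flexibility
#   refractive_index         McMeekin et al., as tabulated by Jones (1975)
#   chromatographic_index    Aboderin (1971) paper-chromatography mobility
#   surrounding_hydrophobicity  Ponnuswamy, Prabhakaran & Manavalan (1980)
#   partial_specific_volume  Cohn & Edsall (1943) (mL/g)
#   vdw_volume_normalized    Fauchere et al. (1988) normalized vdW volume
#   hydrophobicity_fp        Fauchere & Pliska (1983) pi scale
#   hydrophobicity_eisenberg Eisenberg et al. (1984) consensus scale
#   heavy_atoms              side-chain non-hydrogen atom count
#   carbon_atoms             whole-residue carbon atom count
#   net_charge_ph7           formal side-chain charge at pH 7 (His 0.1)
#   aromaticity              aromatic side chain indicator (His 0.5)
#   aliphaticity             aliphatic side chain indicator (A,V,L,I)
#   buriedness_janin         Janin (1979) buried/accessible free energy
#   helix_propensity_ps      Pace & Scholtz (1998) helix propensity (kcal/mol)
#   beta_branching           beta-branched side chain indicator (V,I,T)
#   rotatable_bonds          side-chain rotatable bond count
aa	hydropathy	polarity	composition	molecular_volume	molecular_weight	isoelectric_point	bulkiness	polarity_zimmerman	helix_propensity_cf	sheet_propensity_cf	turn_propensity_cf	residue_volume	accessible_surface_area	hydrophilicity	flexibility	refractive_index	chromatographic_index	surrounding_hydrophobicity	partial_specific_volume	vdw_volume_normalized	hydrophobicity_fp	hydrophobicity_eisenberg	heavy_atoms	carbon_atoms	net_charge_ph7	aromaticity	aliphaticity	buriedness_janin	helix_propensity_ps	beta_branching	rotatable_bonds
A	1.8	8.1	0	31	89.1	6.00	11.50	0.00	1.42	0.83	0.66	88.6	115	-0.5	0.36	4.34	5.1	12.97	0.74	1.00	0.31	0.62	1	3	0	0	1	0.3	0.00	0	0
R	-4.5	10.5	0.65	124	174.2	10.76	14.28	52.00	0.98	0.93	0.95	173.4	225	3.0	0.53	26.66	2.0	11.72	0.70	6.13	-1.01	-2.53	7	6	1	0	0	-1.4	0.21	0	4
N	-3.5	11.6	1.33	56	132.1	5.41	12.82	3.38	0.67	0.89	1.56	114.1	160	0.2	0.46	13.28	0.6	11.42	0.62	2.95	-0.60	-0.78	4	4	0	0	0	-0.5	0.65	0	2
D	-3.5	13.0	1.38	54	133.1	2.77	11.68	49.70	1.01	0.54	1.46	111.1	150	3.0	0.51	12.00	0.7	10.85	0.60	2.78	-0.77	-0.90	4	4	-1	0	0	-0.6	0.69	0	2
C	2.5	5.5	2.75	55	121.2	5.07	13.46	1.48	0.70	1.19	1.19	108.5	135	-1.0	0.35	35.77	0.0	14.63	0.61	2.43	1.54	0.29	2	3	0	0	0	0.9	0.68	0	1
Q	-3.5	10.5	0.89	85	146.2	5.65	14.45	3.53	1.11	1.10	0.98	143.8	180	0.2	0.49	17.56	1.4	11.76	0.67	3.95	-0.22	-0.85	5	5	0	0	0	-0.7	0.39	0	3
E	-3.5	12.3	0.92	83	147.1	3.22	13.57	49.90	1.51	0.37	0.74	138.4	190	3.0	0.50	17.26	1.8	11.89	0.66	3.78	-0.64	-0.74	5	5	-1	0	0	-0.7	0.40	0	3
G	-0.4	9.0	0.74	3	75.1	5.97	3.40	0.00	0.57	0.75	1.56	60.1	75	0.0	0.54	0.00	4.1	12.43	0.64	0.00	0.00	0.48	0	2	0	0	0	0.3	1.00	0	0
H	-3.2	10.4	0.58	96	155.2	7.59	13.69	51.60	1.00	0.87	0.95	153.2	195	-0.5	0.32	21.81	1.6	12.16	0.67	4.66	0.13	-0.40	6	6	0.1	0.5	0	-0.1	0.61	0	2
I	4.5	5.2	0	111	131.2	6.02	21.40	0.13	1.08	1.60	0.47	166.7	175	-1.8	0.46	19.06	9.3	15.67	0.90	4.00	1.80	1.38	4	6	0	0	1	0.7	0.41	1	2
L	3.8	4.9	0	111	131.2	5.98	21.40	0.13	1.21	1.30	0.59	166.7	170	-1.8	0.37	18.78	10.0	14.90	0.90	4.00	1.70	1.06	4	6	0	0	1	0.5	0.21	0	2
K	-3.9	11.3	0.33	119	146.2	9.74	15.71	49.50	1.16	0.74	1.01	168.6	200	3.0	0.47	21.29	1.3	11.36	0.82	4.77	-0.99	-1.50	5	6	1	0	0	-1.8	0.26	0	4
M	1.9	5.7	0	105	149.2	5.74	16.25	1.43	1.45	1.05	0.60	162.9	185	-1.3	0.30	21.64	8.7	14.39	0.75	4.43	1.23	0.64	4	5	0	0	0	0.4	0.24	0	3
F	2.8	5.2	0	132	165.2	5.48	19.80	0.35	1.13	1.38	0.60	189.9	210	-2.5	0.31	29.40	9.6	14.00	0.77	5.89	1.79	1.19	7	9	0	1	0	0.5	0.54	0	2
P	-1.6	8.0	0.39	32.5	115.1	6.30	17.43	1.58	0.57	0.55	1.52	112.7	145	0.0	0.51	10.93	4.9	11.37	0.76	2.72	0.72	0.12	3	5	0	0	0	-0.3	3.16	0	0
S	-0.8	9.2	1.42	32	105.1	5.68	9.47	1.67	0.77	0.75	1.43	89.0	115	0.3	0.51	6.35	3.1	11.23	0.63	1.60	-0.04	-0.18	2	3	0	0	0	-0.1	0.50	0	1
T	-0.7	8.6	0.71	61	119.1	5.60	15.77	1.66	0.83	1.19	0.96	116.1	140	-0.4	0.44	11.01	3.5	11.69	0.70	2.60	0.26	-0.05	3	4	0	0	0	-0.2	0.66	1	1
W	-0.9	5.4	0.13	170	204.2	5.89	21.67	2.10	1.08	1.37	0.96	227.8	255	-3.4	0.31	42.53	9.2	13.93	0.74	8.08	2.25	0.81	10	11	0	1	0	0.3	0.49	0	2
Y	-1.3	6.2	0.20	136	181.2	5.66	18.03	1.61	0.69	1.47	1.14	193.6	230	-2.3	0.42	31.53	8.0	13.42	0.71	6.47	0.96	0.26	8	9	0	1	0	-0.4	0.53	0	2
V	4.2	5.9	0	84	117.1	5.96	21.57	0.13	1.06	1.70	0.50	140.0	155	-1.5	0.39	13.92	8.5	15.71	0.86	3.00	1.22	1.08	3	5	0	0	1	0.6	0.61	1	1
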