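# Published per-partition diversity statistics for Indian oil sardine
# (Sardinella longiceps) mitogenomes (n = 45), used as worked-example inputs
# for the relative-mutation-rate and Ka/Ks arithmetic. Columns: partition,
# segregating sites S, nucleotide diversity pi, haplotype count, haplotype
# diversity Hd, mean pairwise differences K, synonymous substitution rate Ks,
# nonsynonymous rate Ka, Watterson theta, published relative mutation rate
# mu_relative, Tajima's D. NA marks values not reported for a partition.
partition	S	pi	n_hap	Hd	K	Ks	Ka	theta	mu_relative	tajima_d
Genome	1131	0.00606	45	1	100.628	NA	NA	0.00611	1.5	-2.31923
Gene_concatenated	859	0.00682	45	1.00	77.901	0.023	0.001	0.00688	1.12	-2.37011
ATP6	47	0.00599	32	0.940	4.094	0.015	0.003	0.00604	0.9	-2.4994
ATP8	4	0.00132	5	0.211	0.222	0.004	0.001	0.00132	0.22	-1.76368
CO1	78	0.00394	30	0.998	6.054	0.013	0.001	0.00392	0.64	-2.46843
CO2	54	0.00558	24	0.824	3.859	0.014	0.003	0.00562	0.92	-2.5591
CO3	32	0.00455	25	0.001	3.569	0.014	0.001	0.00457	0.75	-2.1433
Control_region	107	0.01597	43	0.998	15.115	NA	NA	0.01631	2.66	-1.5376
CYTB	92	0.00656	39	0.984	7.489	0.022	0.001	0.00662	1.08	-2.357
ND1	87	0.00995	34	0.987	9.784	0.037	0.001	0.01008	1.64	-1.9555
ND2	100	0.00913	38	0.993	9.544	0.033	0.001	0.00925	1.51	-2.2421
ND3	21	0.00512	21	0.841	1.781	0.018	0.001	0.00515	0.84	-2.1182
ND4	143	0.00849	42	0.997	11.719	0.029	0.001	0.00858	1.4	-2.3601
ND4L	7	0.00133	8	0.362	0.396	0.005	0	0.00134	0.22	-2.0336
ND5	170	0.00887	44	0.999	16.293	0.031	0.002	0.00898	1.46	-2.3059
ND6	24	0.0061	28	0.904	3.184	0.022	0	0.0061	0.99	-1.7519
12S_rRNA	11	0.00265	14	0.612	1.046	NA	NA	0.0011	0.18	-1.7332
16S_rRNA	74	0.00288	34	0.967	4.857	NA	NA	0.00289	0.47	-2.572
tRNAs	27	0.00117	20	0.761	1.701	NA	NA	0.00117	0.19	-2.425
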