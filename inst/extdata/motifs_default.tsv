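# Template conserved-block motif configuration for a teleost mitochondrial
# control region: name, IUPAC pattern, maximum mismatches for a hit. The TAS
# pattern is the usual TACAT / ATGTA palindromic core; CSB2 and CSB3 are the
# classic C-rich consensus blocks. These are configurable defaults meant to
# be overridden with species-specific patterns.
name	pattern	max_mismatch
TAS	TACATAAATATGTA	2
CSB_D	CCTGGCATCTGGTTCCT	3
CSB1	TTAATGGTCACGGGACATA	3
CSB2	CAAACCCCCCCTCCCCC	3
CSB3	TGCCAAACCCCAAAAACA	3
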