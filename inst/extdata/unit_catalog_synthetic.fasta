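>unit38_type1 synthetic 38 bp consensus repeat unit (hairpin-capable palindromic core)
TACATGGCCGTTACAAAAACGGCCTATGTATTAGCAAT
>unit40_type3a synthetic 40 bp variant unit (non-compensatory stem substitutions)
TACATGACAGGTACAAAAAAGTCATATGTATTAGCAATCA
>unit40_type3b synthetic 40 bp variant unit (non-compensatory stem substitutions)
TACATTGTCCTTACAAAACCTGACTATGTATTAGCAATGA
>unit40_type3c synthetic 40 bp variant unit (non-compensatory stem substitutions)
TACATGTCCATGACAAAGACAGCTTATGTATTAGCAATTA
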