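>tm_synthetic_22mer helical_region=1-22 | synthetic stand-in for a transmembrane test segment
LFIIVVLIVVVVVVAALFAILL
>soluble_synthetic_22mer helical_region=1-22 | synthetic stand-in for a hydrophilic helical test segment
SEQKDKRTTERKEHNNHSHRRH
>half_tm_synthetic helical_region=1-11 | synthetic half-length hydrophobic segment with polar padding
LFIIVVLIVVVETSQHNKRQDS
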