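# L9 fixture note: the source annotations disagree on the helix span
# (45-67 in one place, 46-67 in another); 46-67 is used here and the
# variant is flagged rather than silently reconciled.
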