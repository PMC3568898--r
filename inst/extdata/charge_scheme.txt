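# Example amino-acid property partition in the flat key-value format read
# by read_property_scheme(): one class per line, class = residues.
positive = KRH
negative = DE
uncharged = ACFGILMNPQSTVWY
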