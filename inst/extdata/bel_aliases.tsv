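# Free-text entity names appearing inside BEL terms, mapped to HGNC-style
# symbols. Lookup is case-insensitive; extend with additional rows as needed.
name	symbol
ets-Domain Protein Elk-4	SAP1A
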