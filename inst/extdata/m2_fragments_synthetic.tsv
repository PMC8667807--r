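# Synthetic stand-in M2 fragments, version 1.0
# These 21-residue fragments are SYNTHETIC: constructed sequences that place the
# documented filter residue of each subunit at filter_offset (1-based) inside an
# M2-like context shared within each receptor family. They exist so that the
# anchoring machinery is exercisable offline; they are NOT the UniProt M2
# sequences and must not be used as biological reference material.
name	filter_offset	m2_fragment
GluN1	12	GALTSSAMWFSNVLLNSGIGE
GluN2A	12	GALTSGAMWFSNVLLNSGIGE
GluN2B	12	GALTTSAMWFSNVLLNSGIGE
GluN2C	12	GALTSSAMWFSNVLLNSGVGE
GluN2D	12	GSLTSSAMWFSNVLLNSGIGE
GluN3A	12	GALTSSAMWFSGVLLNSGIGE
GluN3B	12	GALTSSAMWFSGVLLNSGIGD
GluA1	12	TIFNSFWFGLGQAMYQGSELS
GluA2	12	TLFNSFWFGLGQAMYQGSELS
GluA2*	12	TLFNSFWFGLGRAMYQGSELS
GluA3	12	TIFNSFWFGLGQAMYQGSELT
GluA4	12	TIFNTFWFGLGQAMYQGSELS
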