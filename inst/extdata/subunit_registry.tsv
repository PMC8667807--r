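# ringcharge subunit registry, version 1.0
# filter_residue: one-letter amino acid at the selectivity-filter (N/Q/R) site of the M2 re-entrant loop
# filter_position: residue number within the subunit where printed in the primary literature; NA = unknown
# accession: UniProtKB identifier (Rattus norvegicus), provenance metadata only - never fetched
name	family	filter_residue	filter_position	accession	note
GluN1	GluN1	N	598	P35439	obligatory glycine-binding NMDAR subunit; filter asparagine N598
GluN2A	GluN2	N	614	Q00959	glutamate-binding; position follows the epsilon-1 mutagenesis numbering (N614Q)
GluN2B	GluN2	N	NA	Q00960	glutamate-binding; filter asparagine conserved across GluN2
GluN2C	GluN2	N	NA	Q00961	glutamate-binding; filter asparagine conserved across GluN2
GluN2D	GluN2	N	NA	Q62645	glutamate-binding; filter asparagine conserved across GluN2
GluN3A	GluN3	G	NA	Q9R1M7	glycine-binding regulatory subunit; non-polar glycine at the filter site
GluN3B	GluN3	G	NA	Q8VHN2	glycine-binding regulatory subunit; non-polar glycine at the filter site
GluA1	GluA	Q	NA	P19490	AMPAR subunit; glutamine at the Q/R site
GluA2	GluA	Q	605	P19491	AMPAR subunit, unedited Q form; glutamine at the Q/R site Q605
GluA2*	GluA	R	605	P19491	AMPAR subunit, edited (Q->R) form; arginine at the Q/R site
GluA3	GluA	Q	NA	P19492	AMPAR subunit; glutamine at the Q/R site
GluA4	GluA	Q	NA	P19493	AMPAR subunit; glutamine at the Q/R site
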