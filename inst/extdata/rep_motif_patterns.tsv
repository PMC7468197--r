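motif	regex	region	enabled	low_confidence
motif_I	[FWL]T[LIV]NN	n_half	TRUE	FALSE
motif_II	H.[HQ]	n_half	TRUE	FALSE
motif_III	Y.{2,3}K	n_half	TRUE	FALSE
walker_A	G.{4}GK[TS]	c_half	TRUE	FALSE
walker_B	[AVLIMFWC]{2}D[DE]	c_half	TRUE	FALSE
motif_C	[AVLIMFWC].TSN	c_half	TRUE	FALSE
arg_finger	R	downstream_motif_c	TRUE	FALSE
grs	[FY].{2}K.{4,12}W	n_half	FALSE	TRUE
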