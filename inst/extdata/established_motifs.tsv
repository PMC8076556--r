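name	chain	pattern_alpha	pattern_beta	v_alpha	v_beta	j_alpha	j_beta
R-motif	beta	NA	ASS.R.TDTQY	NA	TRBV7-2,TRBV7-3	NA	TRBJ2-3
Extended R-motif	beta	NA	ASS.R.*	NA	TRBV7-2,TRBV7-3	NA	TRBJ2-3
NDYKLS	alpha	I.NDYKLS	NA	TRAV26-1	NA	TRAJ20	NA
Paired R-motif	paired	NA	ASS.R.TDTQY	TRAV26-1	TRBV7-2,TRBV7-3	NA	TRBJ2-3
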