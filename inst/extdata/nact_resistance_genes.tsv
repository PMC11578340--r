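#gene_id	direction_in_nonresponders
INPP4B	higher_tss_score
ABCA3	higher_tss_score
TADA2B	higher_tss_score
ATP2A3	higher_tss_score
COL18A1	higher_tss_score
ABCF2	higher_tss_score
ZIM2	higher_tss_score
MAP3K12	higher_tss_score
GATAD2A	higher_tss_score
PDLIM7	higher_tss_score
OR5V1	higher_tss_score
PKDREJ	higher_tss_score
ARHGEF10	higher_tss_score
DCLK2	higher_tss_score
KCNH3	higher_tss_score
STK11	higher_tss_score
ARID1A	higher_tss_score
CDH23	higher_tss_score
UNC45A	lower_tss_score
PIK3CA	lower_tss_score
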