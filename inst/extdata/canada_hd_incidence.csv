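interval,year,nphs_observed,nphs_lo,nphs_hi,estimated_nphs_std,estimated_census_std
2001-2003,2001,983,831,1136,1018,927
2003-2005,2003,1025,845,1204,888,779
2005-2007,2005,1003,840,1165,918,783
2007-2009,2007,1031,852,1209,1097,873
2009-2011,2009,1016,802,1230,1023,752
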