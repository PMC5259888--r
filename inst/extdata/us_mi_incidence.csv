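interval,year,all_mi,hospitalized_mi
2000-2001,2000,843,472
2002-2003,2002,998,559
2004-2005,2004,546,306
2006-2007,2006,498,279
2008-2009,2008,543,304
2010-2011,2010,678,380
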