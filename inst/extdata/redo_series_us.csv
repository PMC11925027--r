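# Assumed annual US redo surgical AVR counts removed from the ViV candidate
# pool: SAVR-after-SAVR and SAVR-after-TAVR (surgical explant of a failed
# TAVR). The source registries report only recent totals, so this series is
# a documented ASSUMPTION: SAVR-after-SAVR rises linearly 2,000 (1998) ->
# 4,000 (2023), then holds; SAVR-after-TAVR starts 2015, reaches 1,000 by
# 2023 and 3,000 by 2035 (rising TAVR-explant trend). Swappable via config.
year,savr_after_savr,savr_after_tavr
1998,2000,0
1999,2080,0
2000,2160,0
2001,2240,0
2002,2320,0
2003,2400,0
2004,2480,0
2005,2560,0
2006,2640,0
2007,2720,0
2008,2800,0
2009,2880,0
2010,2960,0
2011,3040,0
2012,3120,0
2013,3200,0
2014,3280,0
2015,3360,111
2016,3440,222
2017,3520,333
2018,3600,444
2019,3680,556
2020,3760,667
2021,3840,778
2022,3920,889
2023,4000,1000
2024,4000,1167
2025,4000,1333
2026,4000,1500
2027,4000,1667
2028,4000,1833
2029,4000,2000
2030,4000,2167
2031,4000,2333
2032,4000,2500
2033,4000,2667
2034,4000,2833
2035,4000,3000
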