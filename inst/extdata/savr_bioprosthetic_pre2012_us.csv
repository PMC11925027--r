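# Annual US bioprosthetic SAVR volumes 1998-2011. ASSUMED linear growth at
# the scale reported by surgical-valve utilization literature (rising tissue
# valve share through the 2000s); the sources behind this model do not print
# per-year values, so this series is a documented approximation.
year,count,provenance
1998,16000,assumed
1999,18000,assumed
2000,20000,assumed
2001,22000,assumed
2002,24000,assumed
2003,26000,assumed
2004,28000,assumed
2005,30000,assumed
2006,32000,assumed
2007,34000,assumed
2008,36000,assumed
2009,38000,assumed
2010,40000,assumed
2011,42000,assumed
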