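# Annual US total surgical AVR volumes, 2012-2020, APPROXIMATIONS at the
# scale of STS Adult Cardiac Surgery Database annual research reports
# (isolated + combined AVR). Bioprosthetic counts are derived downstream as
# 80% of these totals. Exact registry extracts are not redistributable;
# values are rounded literature-scale estimates.
year,count,provenance
2012,65000,observed
2013,67000,observed
2014,68000,observed
2015,70000,observed
2016,69000,observed
2017,67000,observed
2018,65000,observed
2019,62000,observed
2020,55000,observed
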