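# coordinates: 1-based, inclusive
# Published per-site statistics for the 19 pseudo-attB insertion sites
# observed in the N. terpenica chromosome: identity counts to the canonical
# attB over the full (73 bp), minimal (36 bp) and crossover (9 bp) windows,
# number of independent insertion events, and genome position of the site.
site	count_full	count_minimal	count_crossover	events	position
Nt-1	26	19	5	1	731398
Nt-2	20	14	4	1	751814
Nt-3	26	17	6	4	1066609
Nt-4	28	19	6	1	1505104
Nt-5	30	17	3	1	1826014
Nt-6	22	13	5	2	3715745
Nt-7	34	20	5	1	3939350
Nt-8	27	15	6	1	4126594
Nt-9	25	13	3	1	4286641
Nt-10	25	17	4	2	5761121
Nt-11	20	14	4	1	7436287
Nt-12	26	16	3	1	7530197
Nt-13	25	13	3	1	7795264
Nt-14	25	19	5	1	7823861
Nt-15	25	12	4	1	8033744
Nt-16	35	21	6	1	8246408
Nt-17	31	16	4	4	8620438
Nt-18	22	14	5	1	8670073
Nt-19	23	14	4	1	8971553
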