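# Curated subset of literature-validated nAChR pentameric assemblies
# (synthetic fixture: a small hand-assembled catalog for examples and tests,
# not an exhaustive compilation). Each assembly lists its subunit genes and
# copy numbers; copies sum to 5.
assembly	subunit	copies
a7	chrna7	5
a9	chrna9	5
a9a10	chrna9	2
a9a10	chrna10	3
a4b2_hs	chrna4	2
a4b2_hs	chrnb2	3
a4b2_ls	chrna4	3
a4b2_ls	chrnb2	2
a3b4	chrna3	2
a3b4	chrnb4	3
a6b2b3	chrna6	2
a6b2b3	chrnb2	2
a6b2b3	chrnb3	1
muscle	chrna1	2
muscle	chrnb1	1
muscle	chrnd	1
muscle	chrng	1
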