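# Evidence table for 60 candidate FoxJ1 proteins from a published
# eukaryote-wide genome survey (56 organisms; paralogous proteins on
# separate rows). Qualitative phylogeny cells are kept verbatim; the loader
# maps "FoxJ1"/"Foxj1" to grouped = TRUE and "Sister to ..."/"Unresolved"/
# blank to grouped = FALSE. Full-length phylogeny was only scored for the
# fungal proteins. Bootstrap values are percentages.
sno	organism	supergroup	group	phylum	paralog	evalue	rbh_call	domain_label	domain_support	full_label	full_support
1	Trichoplax adhaerens	Opisthokonta	Animalia	Placozoa	1	8E-38	FoxJ1	FoxJ1	99
2	Hydra magnipapillata	Opisthokonta	Animalia	Cnidaria	1	9E-32	FoxJ1	FoxJ1	49
3	Nematostella vectensis	Opisthokonta	Animalia	Cnidaria	1	3E-39	FoxJ1	FoxJ1	99
4	Capitella sp. I	Opisthokonta	Animalia	Annelida	1	4E-47	FoxJ1	FoxJ1	99
5	Lottia gigantea	Opisthokonta	Animalia	Mollusca	1	2E-44	FoxJ1	FoxJ1	99
6	Strongylocentrotus purpuratus	Opisthokonta	Animalia	Echinodermata	1	1E-37	FoxJ1	FoxJ1	100
7	Daphnia pulex	Opisthokonta	Animalia	Arthropoda	1	9E-36	FoxJ1	FoxJ1	97
8	Tribolium castaneum	Opisthokonta	Animalia	Arthropoda	1	2E-32	FoxJ1	FoxJ1	99
9	Pediculus humanus corporis	Opisthokonta	Animalia	Arthropoda	1	1E-34	FoxJ1	FoxJ1	99
10	Branchiostoma floridae	Opisthokonta	Animalia	Chordata	1	1E-37	FoxJ1	FoxJ1	99
11	Danio rerio	Opisthokonta	Animalia	Chordata	1	3E-50	FoxJ1	FoxJ1	100
11	Danio rerio	Opisthokonta	Animalia	Chordata	2	1E-43	FoxJ1	FoxJ1	99
12	Tetraodon nigroviridis	Opisthokonta	Animalia	Chordata	1	1E-47	FoxJ1	FoxJ1	99
12	Tetraodon nigroviridis	Opisthokonta	Animalia	Chordata	2	6E-41	FoxJ1	FoxJ1	99
13	Fugu rubripes	Opisthokonta	Animalia	Chordata	1	1E-58	FoxJ1	FoxJ1	100
13	Fugu rubripes	Opisthokonta	Animalia	Chordata	2	4.16E-51	FoxJ1	FoxJ1	99
14	Xenopus tropicalis	Opisthokonta	Animalia	Chordata	1	5E-50	FoxJ1	FoxJ1	100
14	Xenopus tropicalis	Opisthokonta	Animalia	Chordata	2	4E-41	FoxJ1	FoxJ1	99
15	Gallus gallus	Opisthokonta	Animalia	Chordata	1	1E-49	FoxJ1	FoxJ1	100
16	Homo sapiens	Opisthokonta	Animalia	Chordata	1	5E-51	FoxJ1	FoxJ1	100
17	Mus musculus	Opisthokonta	Animalia	Chordata	1	3E-51	FoxJ1	FoxJ1	100
18	Rattus norvegicus	Opisthokonta	Animalia	Chordata	1	1E-51	FoxJ1	FoxJ1	100
19	Bos taurus	Opisthokonta	Animalia	Chordata	1	1E-51	FoxJ1	FoxJ1	100
20	Canis familiaris	Opisthokonta	Animalia	Chordata	1	1E-50	FoxJ1	FoxJ1	100
21	Pongo pygmaeus	Opisthokonta	Animalia	Chordata	1	3.6E-75	FoxJ1	FoxJ1	100
22	Cavia porcellus	Opisthokonta	Animalia	Chordata	1	2.8E-75	FoxJ1	FoxJ1	100
23	Erinaceus europaeus	Opisthokonta	Animalia	Chordata	1	4.3E-58	FoxJ1	FoxJ1	100
24	Loxodonta africana	Opisthokonta	Animalia	Chordata	1	3.6E-75	FoxJ1	FoxJ1	100
25	Gorilla gorilla	Opisthokonta	Animalia	Chordata	1	4.4E-75	FoxJ1	FoxJ1	100
26	Microcebus murinus	Opisthokonta	Animalia	Chordata	1	3.6E-68	FoxJ1	FoxJ1	100
27	Myotis lucifugus	Opisthokonta	Animalia	Chordata	1	4.7E-71	FoxJ1	FoxJ1	100
28	Ochotona princeps	Opisthokonta	Animalia	Chordata	1	2.4E-75	FoxJ1	FoxJ1	100
29	Procavia capensis	Opisthokonta	Animalia	Chordata	1	3E-74	FoxJ1	FoxJ1	100
30	Pteropus vampyrus	Opisthokonta	Animalia	Chordata	1	6.1E-70	FoxJ1	FoxJ1	100
31	Tupaia belangeri	Opisthokonta	Animalia	Chordata	1	1.5E-46	FoxJ1	FoxJ1	100
32	Felis catus	Opisthokonta	Animalia	Chordata	1	1.8E-59	FoxJ1	FoxJ1	100
33	Equus caballus	Opisthokonta	Animalia	Chordata	1	8E-52	FoxJ1	FoxJ1	100
34	Macaca mulatta	Opisthokonta	Animalia	Chordata	1	8E-52	FoxJ1	FoxJ1	100
35	Tursiops truncatus	Opisthokonta	Animalia	Chordata	1	2.5E-74	FoxJ1	FoxJ1	100
36	Monodelphis domestica	Opisthokonta	Animalia	Chordata	1	9E-52	FoxJ1	FoxJ1	100
37	Ornithorhynchus anatinus	Opisthokonta	Animalia	Chordata	1	6E-51	FoxJ1	FoxJ1	100
38	Oryctolagus cuniculus	Opisthokonta	Animalia	Chordata	1	1E-51	FoxJ1	FoxJ1	100
39	Pan troglodytes	Opisthokonta	Animalia	Chordata	1	2E-51	FoxJ1	FoxJ1	100
40	Taeniopygia guttata	Opisthokonta	Animalia	Chordata	1	3E-38	FoxJ1	FoxJ1	99
41	Aspergillus clavatus	Opisthokonta	Fungi	Ascomycota	1	8E-27	FoxJ1	Sister to FoxJ1-J3, FoxK1-K2		Sister to FoxJ2 and FoxJ3	44
42	Aspergillus niger	Opisthokonta	Fungi	Ascomycota	1	1E-27	FoxJ1	Sister to FoxJ1-J3, FoxK1-K2		Sister to FoxJ2 and FoxJ3	60
43	Candida glabrata	Opisthokonta	Fungi	Ascomycota	1	1E-25	FoxJ1	Sister to FoxK1-K2		Sister to FoxP1-P4, FoxR1-R2	51
44	Eremothecium gossypii	Opisthokonta	Fungi	Ascomycota	1	5E-26	FoxJ1	FoxJ1	31	Foxj1	66
45	Saccharomyces cerevisiae	Opisthokonta	Fungi	Ascomycota	1	2E-24	FoxJ1	Sister to FoxK1-K2		Foxj1	48
46	Schizosaccharomyces pombe	Opisthokonta	Fungi	Ascomycota	1	7E-25	FoxD2	Foxj1	52	Unresolved
47	Aspergillus oryzae	Opisthokonta	Fungi	Ascomycota	1	3E-27	FoxJ1	Sister to FoxJ1-J3, FoxK1-K2		Sister to FoxJ2 and FoxJ3	47
48	Aspergillus terreus	Opisthokonta	Fungi	Ascomycota	1	6E-27	FoxJ1	Sister to FoxJ1-J3, FoxK1-K2		Sister to FoxJ2 and FoxJ3	46
49	Coccidioides immitis	Opisthokonta	Fungi	Ascomycota	1	2E-25	FoxJ1	FoxJ1	32	Sister to FoxJ2 and FoxJ3	47
50	Coccidioides posadasii	Opisthokonta	Fungi	Ascomycota	1	3E-25	FoxJ1	FoxJ1	32	Foxj1	53
51	Schizosaccharomyces japonicus	Opisthokonta	Fungi	Ascomycota	1	3E-23	FoxJ1	Sister to FoxO1, O3, O4, O6		Sister to FoxP1-P4, FoxR1-R2	59
52	Stagonospora nodorum	Opisthokonta	Fungi	Ascomycota	1	9E-23	FoxJ1	Sister to FoxJ1-J3, FoxK1-K2		Unresolved
53	Laccaria bicolor	Opisthokonta	Fungi	Basidiomycota	1	4E-15	FoxJ1	Sister to FoxP1-P4		Foxh1	52
54	Encephalitozoon cuniculi	Opisthokonta	Fungi	Microsporidia	1	2E-26	FoxJ1	Sister to FoxJ1-J3, FoxK1-K2		Sister to FoxJ2 and FoxJ3	39
55	Allomyces macrogynus	Opisthokonta	Fungi	Blastocladiomycota	1	4.01858E-25	FoxJ1	Sister to FoxJ2-J3		Sister to FoxP1-P4, FoxR1-R2	97
56	Monosiga brevicollis	Opisthokonta	Choanozoa	Choanozoa	1	2.95E-29	FoxJ1	Sister to FoxJ1-J3, FoxK1-K2
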