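gene_name	orf_id	class	category	alias
odv-e18	orf13	core	structure
49k	orf14	core	structure
odv-ec43	orf47	core	structure
p48/p45	orf74	core	structure
p40;bv/odv-c42	orf76	core	structure
p6.9	orf77	core	structure
38k	orf79	core	structure
odv-e25	orf82	core	structure
p18	orf83	core	structure
p33	orf84	core	structure
vp39	orf87	core	structure
odv-ec27	orf88	core	structure
ac81	orf93	core	structure
gp41	orf94	core	structure
ac78	orf95	core	structure
desmop	orf100	core	structure
ac53	orf120	core	structure
vp1054	orf123	core	structure
lef-2	orf34	core	replication
lef-1	orf64	core	replication
helicase	orf81	core	replication
dna-pol	orf99	core	replication
alk-exo	orf114	core	replication
p47	orf60	core	transcription
lef-5	orf78	core	transcription
lef-4	orf86	core	transcription
vlf1	orf96	core	transcription
lef-9	orf106	core	transcription
lef-8	orf117	core	transcription
pif-5	orf16	core	oral_infection
pif-3	orf30	core	oral_infection
pif-2	orf41	core	oral_infection
ac110	orf45	core	oral_infection
p74	orf53	core	oral_infection
pif-1	orf65	core	oral_infection
pif-4	orf80	core	oral_infection
pif-8	orf91	core	oral_infection
pif-6	orf103	core	oral_infection
granulin	orf1	lepidopteran_conserved	structure
pk-1	orf3	lepidopteran_conserved	structure
calyx/pep-1	orf20	lepidopteran_conserved	structure
F protein	orf27	lepidopteran_conserved	structure
bv-e31	orf61	lepidopteran_conserved	structure
p24	orf62	lepidopteran_conserved	structure
p12	orf75	lepidopteran_conserved	structure
tlp-20	orf92	lepidopteran_conserved	structure
fp25k	orf118	lepidopteran_conserved	structure
lef-11	orf51	lepidopteran_conserved	replication
dbp	orf71	lepidopteran_conserved	replication
lef-3	orf102	lepidopteran_conserved	replication
me53	orf128	lepidopteran_conserved	replication
39k	orf50	lepidopteran_conserved	transcription
lef-6	orf70	lepidopteran_conserved	transcription
38.7k	orf63	lepidopteran_conserved	auxiliary
p10	orf17	other	structure
pep-2	orf23	other	structure
vp80	orf24	other	structure
ie-1	orf6	other	replication
dna ligase	orf108	other	replication
helicase-2	orf115	other	replication
odv-e66	orf31	other	oral_infection
chitinase	orf9	other	auxiliary
iap-3	orf11	other	auxiliary
gp37	orf12	other	auxiliary
bro	orf26	other	auxiliary
p13	orf39	other	auxiliary
ubiquitin	orf46	other	auxiliary
sod	orf52	other	auxiliary
fgf-1	orf66	other	auxiliary
iap-1	orf85	other	auxiliary	iap-6
iap-2	orf105	other	auxiliary	iap-5
fgf-2	orf111	other	auxiliary
fgf-3	orf126	other	auxiliary
egt	orf127	other	auxiliary
orf22	orf22	unique	unique
orf40	orf40	unique	unique
orf56	orf56	unique	unique
orf101	orf101	unique	unique
orf124	orf124	unique	unique
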