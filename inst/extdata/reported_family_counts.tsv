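# Printed per-family summary counts for the five B. napus TF families,
# transcribed from the published inventory tables. Used as inputs to the
# arithmetic acceptance checks; columns:
#   n_genes            genes identified per family
#   n_unanchored       genes on unanchored scaffolds
#   novel/conserved/multi_copy   synteny category counts (focal species)
#   lost_A/lost_C      ancestor genes lost, per sub-genome
#   unique_deg         DEGs under at least one treatment (probability 0.6)
#   crucial            crucial DEGs after GO filtering
#   crucial_cold/heat/drought/salt/aba   crucial DEGs per treatment
family	n_genes	n_unanchored	novel	conserved	multi_copy	lost_A	lost_C	unique_deg	crucial	crucial_cold	crucial_heat	crucial_drought	crucial_salt	crucial_aba
AP2/EREBP	518	105	33	66	419	12	14	140	93	41	62	11	17	9
bZIP	252	45	22	26	204	7	5	75	42	11	32	2	7	10
MYB	721	151	65	54	602	8	16	141	94	39	61	9	9	16
NAC	398	72	29	30	339	1	16	68	48	22	40	4	5	5
WRKY	278	46	19	24	235	2	4	50	38	18	27	4	2	6
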