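genome_id	species	phylum	has_glnrs	has_glurs2	has_gatcab	trna_gln_1_72	pzbd_deleted
acl	Acholeplasma laidlawii	tenericutes	TRUE	FALSE	FALSE	GC	TRUE
pml	Phytoplasma mali	tenericutes	TRUE	FALSE	FALSE	GC	TRUE
poy	Onion yellows phytoplasma OY-M	tenericutes	TRUE	FALSE	FALSE	GC	TRUE
amu	Akkermansia muciniphila	verrucomicrobia	TRUE	FALSE	TRUE	GC	TRUE
phm	Phycisphaera mikurensis	planctomycetes	TRUE	FALSE	TRUE	GC	TRUE
nse1	Neorickettsia sennetsu GluRS1	alpha-proteobacteria	FALSE	TRUE	TRUE	UA	TRUE
min	Methylacidiphilum infernorum	verrucomicrobia	FALSE	FALSE	TRUE	AU	TRUE
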