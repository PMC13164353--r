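# Default protease specificity rules (approximate published specificities).
# p1_set: residues whose C-terminal bond is cleaved; p1prime_exclusions:
# residues blocking cleavage when immediately C-terminal.
enzyme	p1_set	p1prime_exclusions
pepsin pH1.3	FL
chymotrypsin A	FYW	P
trypsin	KR	P
papain	RKFYWLVIAG
stem bromelain	AGKRLVIFY
subtilisin	FYWLIVATM
proteinase K	AFILVWY
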