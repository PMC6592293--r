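gene	protein_change	somatic_status
KRAS	p.G12D	cosmic_confirmed
KRAS	p.G12V	cosmic_confirmed
KRAS	p.G12R	cosmic_confirmed
KRAS	p.G12A	cosmic_confirmed
KRAS	p.G12C	cosmic_confirmed
KRAS	p.G12S	cosmic_confirmed
KRAS	p.G12T	cosmic_confirmed
KRAS	p.G13D	cosmic_confirmed
KRAS	p.Q61H	cosmic_confirmed
KRAS	p.Q61R	cosmic_confirmed
KRAS	p.Q61L	cosmic_confirmed
KRAS	p.Q61K	cosmic_confirmed
KRAS	p.Q61C	cosmic_confirmed
GNAS	p.R201C	cosmic_confirmed
GNAS	p.R201H	cosmic_confirmed
BRAF	p.V600E	cosmic_confirmed
BRAF	p.D594G	cosmic_confirmed
TP53	p.R175H	cosmic_confirmed
TP53	p.R248Q	cosmic_confirmed
TP53	p.R273H	cosmic_confirmed
TP53	p.R282W	cosmic_confirmed
SMAD4	p.R361H	cosmic_confirmed
SMAD4	p.R361C	cosmic_confirmed
CDKN2A	p.H83Y	cosmic_confirmed
CDKN2A	p.D108N	cosmic_confirmed
PIK3CA	p.E545K	cosmic_confirmed
PIK3CA	p.H1047R	cosmic_confirmed
PTEN	p.R130G	cosmic_confirmed
VHL	p.R167W	cosmic_confirmed
VHL	p.S65L	cosmic_confirmed
APC	p.R1450X	cosmic_confirmed
ATM	p.R337C	cosmic_confirmed
RB1	p.R455X	cosmic_confirmed
ARID1A	p.R1989X	cosmic_confirmed
TP53	p.P72R	germline_snp
KIT	p.M541L	germline_snp
APC	p.V1822D	germline_snp
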