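gene	aa_change	class	source
PIK3CA	R38H	Path/GoF	curated-snapshot
PIK3CA	R38C	Path/GoF	curated-snapshot
PIK3CA	E81K	Path/GoF	curated-snapshot
PIK3CA	R88Q	Path/GoF	curated-snapshot
PIK3CA	R93W	Path/GoF	curated-snapshot
PIK3CA	G106V	Path/GoF	curated-snapshot
PIK3CA	R108H	Path/GoF	curated-snapshot
PIK3CA	K111E	Path/GoF	curated-snapshot
PIK3CA	G118D	Path/GoF	curated-snapshot
PIK3CA	N345K	Path/GoF	curated-snapshot
PIK3CA	C420R	Path/GoF	curated-snapshot
PIK3CA	E453K	Path/GoF	curated-snapshot
PIK3CA	E542K	Path/GoF	curated-snapshot
PIK3CA	E545K	Path/GoF	curated-snapshot
PIK3CA	E545A	Path/GoF	curated-snapshot
PIK3CA	E545G	Path/GoF	curated-snapshot
PIK3CA	E545Q	Path/GoF	curated-snapshot
PIK3CA	Q546K	Path/GoF	curated-snapshot
PIK3CA	Q546R	Path/GoF	curated-snapshot
PIK3CA	Q546E	Path/GoF	curated-snapshot
PIK3CA	Q546P	Path/GoF	curated-snapshot
PIK3CA	E726K	Path/GoF	curated-snapshot
PIK3CA	G914R	Path/GoF	curated-snapshot
PIK3CA	E970K	Path/GoF	curated-snapshot
PIK3CA	M1043I	Path/GoF	curated-snapshot
PIK3CA	M1043V	Path/GoF	curated-snapshot
PIK3CA	H1047R	Path/GoF	curated-snapshot
PIK3CA	H1047L	Path/GoF	curated-snapshot
PIK3CA	H1047Y	Path/GoF	curated-snapshot
PIK3CA	G1049R	Path/GoF	curated-snapshot
PIK3CA	G1049S	Path/GoF	curated-snapshot
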