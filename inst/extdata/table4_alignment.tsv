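channel	domain	segment	start	sequence
a1C	1	o	1	PLLHIALLVL FVIIIYAIIG LELFMGK
a1G	1	o	1	MLGNVLLLCF FVFFIFGIVG VQLWAGL
a1C	2	o	1	SIASLLLLLF LFIIIFSLLG MQLFGGK
a1G	2	o	1	NVATFCMLLM LFIFIFSILG MHLFGCK
a1C	3	o	1	TIGNIVIVTT LLQFMFACIG VALFKGK
a1G	3	o	1	PIGNIVVICC AFFIIFGILG VQLFKGK
a1C	4	o	1	ALPYVALLIV MLFFIYAVII GMQVFGK
a1G	4	o	1	QVGNLGLLFM LLFFIFAALG VELFGDL
a1C	1	p	33	FDNFAFAMLT VFQCITMEGW TDVLY
a1G	1	p	33	FDNIGYAWIA IFQVITLEGW VDIMY
a1C	2	p	33	FDNFPQSLLT VFQILTGEDW NSVMY
a1G	2	p	33	FDSLLWAIVT VFQILTQEDW NKVLY
a1C	3	p	33	FDNVLAAMMA LFTVSTFEGW PELLY
a1G	3	p	33	FDNLGQALMS LFVLASKDGW VDIMY
a1C	4	p	33	FQTFPQAVLL LFRCATGEAW QDIML
a1G	4	p	33	FRNFGMAFLT LFRVSTGDNW NGIMK
a1C	1	i	1	ELPWVYFVSL VIFGSFFVLN LVLGVLSGEF
a1G	1	i	1	FYNFIYFILL IIVGSFFMIN LCLVVIATQF
a1C	2	i	1	MLVCIYFIIL FICGNYILLN VFLAIAYDNL
a1G	2	i	1	S WAALYFIAL MTFGNYVLFN LLVAILVEGF
a1C	3	i	1	VEISIFFIIY IIIIAFFMMN IFVGFVIVTF
a1G	3	i	1	PWMLLYFISF LLIVAFFVLN MFVGVVVENF
a1C	4	i	1	SFAVFYFISF YMLCAFLIIN LFVAVIMDNF
a1G	4	i	1	VI SPIYFVSF VLTAQFVLVN VVIAVLMKHL
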