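# Bovine rhodopsin (Bos taurus, UniProt P02699, 348 aa) — the numbering
# standard used throughout the opsin literature.
# Counterion E113 distinguishes monostable (E/D present) from bistable
# (uncharged) pigments; the four residue pairs and the NPXXY motif are
# required for G-protein activation by signaling rhodopsins.
scheme_id	bovine_rhodopsin
reference	MNGTEGPNFYVPFSNKTGVVRSPFEAPQYYLAEPWQFSMLAAYMFLLIMLGFPINFLTLYVTVQHKKLRTPLNYILLNLAVADLFMVFGGFTTTLYTSLHGYFVFGPTGCNLEGFFATLGGEIALWSLVVLAIERYVVVCKPMSNFRFGENHAIMGVAFTWVMALACAAPPLVGWSRYIPEGMQCSCGIDYYTPHEETNNESFVIYMFVVHFIIPLIVIFFCYGQLVFTVKEAAAQQQESATTQKAEKEVTRMVIIMVIAFLICWLPYAGVAFYIFTHQGSDFGPIFMTIPAFFAKTSAVYNPVIYIMMNKQFRNCMVTTLCCGKNPLGDDEASTTVSKTETSQVAPA
site	E113=113:E:counterion
site	D83=83:D:gprotein
site	N302=302:N:gprotein
site	R135=135:R:gprotein
site	Y223=223:Y:gprotein
site	K231=231:K:gprotein
site	E247=247:E:gprotein
site	Y306=306:Y:gprotein
site	F313=313:F:gprotein
site	P303=303:P:motif
pair	D83/N302=D83,N302
pair	R135/Y223=R135,Y223
pair	K231/E247=K231,E247
pair	Y306/F313=Y306,F313
motif	NPXXY=302:N,303:P,306:Y;wild=304,305
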