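taxon	direction
Escherichia	up
Klebsiella	up
Enterococcus	up
Veillonella	up
Haemophilus	up
Fusobacterium	up
Streptococcus	up
Faecalibacterium	down
Roseburia	down
Ruminococcus	down
Blautia	down
Coprococcus	down
Bacteroides	down
Dorea	down
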