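haplotype,haplogroup,species,accession
A1,A,Aplochiton zebra,HQ540334
A2,A,Aplochiton zebra,HQ540335
A3,A,Aplochiton zebra,HQ540336
A4,A,Aplochiton zebra,HQ540337
A5,A,Aplochiton zebra,HQ540338
A6,A,Aplochiton zebra,HQ540339
A7,A,Aplochiton zebra,KC243102
A8,A,Aplochiton zebra,KC243103
A9,A,Aplochiton zebra,KC243104
A10,A,Aplochiton zebra,JQ048551
B1,B,Aplochiton taeniatus,HQ540331
B2,B,Aplochiton taeniatus,HQ540332
B3,B,Aplochiton taeniatus,HQ540333
B5,B,Aplochiton taeniatus,JQ048548
B6,B,Aplochiton taeniatus,KC243101
B7,B,Aplochiton taeniatus,JQ048547
C1,C,Aplochiton marinus,JQ048549
C2,C,Aplochiton marinus,JQ048552
C3,C,Aplochiton marinus,JQ048550
NA,outgroup,Galaxias platei,FJ178349
NA,outgroup,Galaxias maculatus,AP004104
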