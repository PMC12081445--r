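ntrk_gene	tkd_first_exon	tkd_last_exon	required_first_exon
NTRK1	9	17	12
NTRK2	16	20	18
NTRK3	15	19	16
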