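# version: 2025.05
partner_gene	ntrk_gene	evidence_class	source_tags
LMNA	NTRK1	canonical	COSMIC;GENIE
PEAR1	NTRK1	canonical	COSMIC
RABGAP1L	NTRK1	canonical	COSMIC;GENIE
TP53	NTRK1	canonical	GENIE
EML4	NTRK1	canonical	COSMIC;GENIE
TPM3	NTRK1	canonical	COSMIC;GENIE;trials
LGR6	NTRK1	canonical	COSMIC
TPR	NTRK1	canonical	COSMIC;GENIE
IRF2BP2	NTRK1	clinical_validity	trials
GKAP1	NTRK2	clinical_validity	trials
SQSTM1	NTRK2	canonical	COSMIC;trials
GNAQ	NTRK2	canonical	COSMIC
SASH1	NTRK3	canonical	COSMIC
ETV6	NTRK3	canonical	COSMIC;GENIE;trials
EML4	NTRK3	canonical	COSMIC;GENIE
ARNT2	NTRK3	canonical	GENIE
SQSTM1	NTRK3	canonical	COSMIC
TARSL2	NTRK3	clinical_validity	trials
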