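gene	rsid	effect_allele	other_allele	eaf	in_ea_set	in_eaa_set	ref_beta	ref_se	imputed
NEGR1	rs2568958	A	G	0.91	TRUE	FALSE	NA	NA	FALSE
TNNI3K	rs1514175	A	G	0.78	TRUE	FALSE	NA	NA	FALSE
PTBP2	rs1555543	C	A	0.88	TRUE	FALSE	NA	NA	FALSE
SEC16B	rs574367	T	G	0.20	TRUE	TRUE	NA	NA	FALSE
TMEM18	rs11127485	C	T	0.91	TRUE	FALSE	NA	NA	FALSE
RBJ	rs6545814	G	A	0.42	TRUE	TRUE	NA	NA	FALSE
ETV5	rs7647305	C	T	0.95	TRUE	FALSE	NA	NA	FALSE
GNPDA2	rs10938397	G	A	0.30	TRUE	FALSE	NA	NA	FALSE
FLJ35779	rs2112347	T	G	0.43	TRUE	FALSE	NA	NA	FALSE
PCSK1	rs261967	C	A	0.42	FALSE	TRUE	NA	NA	FALSE
CDKAL1	rs9356744	T	C	0.40	FALSE	TRUE	NA	NA	FALSE
NUDT3	rs206936	G	A	0.53	TRUE	FALSE	NA	NA	FALSE
TFAP2B	rs987237	G	A	0.16	TRUE	FALSE	0.13	NA	FALSE
LRRN6C	rs10968576	G	A	0.22	TRUE	FALSE	NA	NA	FALSE
KLF9	rs11142387	C	A	0.33	FALSE	TRUE	NA	NA	FALSE
RPL27A	rs4929949	C	T	0.41	TRUE	FALSE	NA	NA	FALSE
BDNF	rs10501087	C	T	0.53	TRUE	TRUE	NA	NA	FALSE
MTCH2	rs3817334	T	C	0.32	TRUE	FALSE	NA	NA	FALSE
FAIM2	rs7138803	A	G	0.28	TRUE	FALSE	NA	NA	FALSE
MTIF3	rs4771122	G	A	0.19	TRUE	FALSE	NA	NA	FALSE
MAP2K5	rs4776970	T	C	0.24	TRUE	TRUE	NA	NA	FALSE
GP2	rs12597579	C	T	0.29	FALSE	TRUE	NA	NA	FALSE
SH2B1	rs4788102	A	G	0.14	TRUE	FALSE	NA	NA	FALSE
FTO	rs9939609	A	T	0.11	TRUE	TRUE	0.39	NA	FALSE
MC4R	rs17782313	C	T	0.23	TRUE	TRUE	NA	NA	FALSE
KCTD15	rs29941	G	A	0.24	TRUE	FALSE	NA	NA	FALSE
GIPR	rs11671664	G	A	0.54	TRUE	TRUE	NA	NA	FALSE
TMEM160	rs3810291	A	G	0.29	TRUE	FALSE	NA	NA	FALSE
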