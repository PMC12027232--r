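gene_id	description	mean_log2tpm	sd_log2tpm	cv_printed	candidate
rps2	ribosomal protein S2	9.20	0.57	0.062	TRUE
rack1	receptor for activated protein kinase c1	7.99	0.65	0.081	TRUE
rpl6	ribosomal protein L6	8.94	0.73	0.082	TRUE
eef1b	eukaryotic translation elongation factor 1beta	8.41	0.71	0.084	TRUE
eif4a	eukaryotic translation initiation factor 4a	6.11	0.53	0.087	TRUE
rpl9	ribosomal protein L9	8.62	0.75	0.087	TRUE
rps18	ribosomal protein S18	9.17	0.87	0.095	TRUE
rplp0	ribosomal protein lateral stalk subunit P0	7.57	0.72	0.095	TRUE
eif5a	eukaryotic translation initiation factor 5a	6.02	0.60	0.099	TRUE
eef1a	eukaryotic elongation factor 1alpha	10.32	1.06	0.103	FALSE
actb	beta-actin	9.77	3.42	0.350	FALSE
gapdh	glyceraldehyde-3-phosphate dehydrogenase	8.55	2.10	0.246	FALSE
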