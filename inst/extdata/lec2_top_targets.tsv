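gene_id	withPeakN	sumRP	RP_rank	log2FoldChange	padj	diff_rank	rankProduct	rankOf_rankProduct	gene_category
AT2G30470	7	7.026484	2	3.699854	5.27E-64	2	4	1	up
AT5G08460	6	7.046663	1	4.554615	3.60E-51	8	8	2	up
AT1G11170	2	3.464122	54	3.26064	2.76E-62	3	162	3	up
AT3G43270	4	2.352608	194	4.30147	1.03E-108	1	194	4	up
AT5G15830	2	3.87378	33	6.779295	1.88E-56	6.5	214.5	5	up
AT2G13810	3	5.147604	10	4.602503	1.83E-21	42	420	6	up
AT5G23360	5	3.082765	88	3.312275	1.88E-56	6.5	572	7	up
AT5G07550	5	3.759361	36	8.162229	3.32E-36	16	576	8	up
AT5G57785	6	5.970996	6	5.74865	2.69E-10	100	600	9	up
AT3G59850	2	2.594872	156	4.139314	1.55E-59	4	624	10	up
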