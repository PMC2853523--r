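strain	key_feature	total_proteins	n_mca	pct_mca	n_mutated	n_additional_domains
Prochlorococcus marinus str. MIT 9215	Unicellular Marine	1983	0	0	0	0
Prochlorococcus marinus str. MIT 9301	Unicellular Marine	1907	0	0	0	0
Prochlorococcus marinus str. AS 9601	Unicellular Marine	1921	0	0	0	0
Prochlorococcus marinus str. MIT 9312	Unicellular Marine	1810	0	0	0	0
Prochlorococcus marinus subsp. pastoris str. CCMP 1986	Unicellular Marine	1717	0	0	0	0
Prochlorococcus marinus str. MIT 9515	Unicellular Marine	1906	0	0	0	0
Prochlorococcus marinus str. NATL2A	Unicellular Marine	2163	0	0	0	0
Prochlorococcus marinus str. NATL1A	Unicellular Marine	2193	0	0	0	0
Prochlorococcus marinus subsp. marinus str. CCMP1375	Unicellular Marine	1883	0	0	0	0
Prochlorococcus marinus str. MIT 9211	Unicellular Marine	1855	0	0	0	0
Prochlorococcus marinus str. MIT 9313	Unicellular Marine	2269	0	0	0	0
Prochlorococcus marinus str. MIT 9303	Unicellular Marine	2997	0	0	0	0
Synechococcus sp. WH 7803	Unicellular Marine	2533	0	0	0	0
Synechococcus sp. CC 9311	Unicellular Marine	2892	0	0	0	0
Synechococcus sp. WH 8102	Unicellular Marine	2519	0	0	0	0
Synechococcus sp. CC 9902	Unicellular Marine	2307	0	0	0	0
Synechococcus sp. CC 9605	Unicellular Marine	2645	0	0	0	0
Synechococcus sp. RCC 307	Unicellular Marine	2535	0	0	0	0
Synechococcus elongatus PCC 6301	Unicellular Freshwater	2527	1	0.04	1	0
Synechococcus elongatus PCC 7942	Unicellular Freshwater	2612	1	0.04	1	0
Acaryochloris marina MBIC 11017	Unicellular Symbiont	6254	8	0.13	1	29
Microcystis aeruginosa NIES-843	Unicellular Freshwater	6312	2	0.03	1	0
Synechocystis sp. PCC 6803	Unicellular Freshwater	3172	1	0.03	1	0
Cyanothece sp. ATCC 51142	Unicellular Marine	4762	3	0.06	2	16
Synechococcus sp. PCC 7002	Unicellular Marine	2823	1	0.04	1	0
Thermosynechococcus elongatus BP-1	Unicellular Hot spring	2475	0	0	0	0
Trichodesmium erythraeum IMS 101	Filamentous Nonheterocystous	4451	10	0.22	1	62
Nostoc punctiforme PCC 73102	Filamentous Heterocystous Symbiotic	6087	9	0.15	2	6
Nostoc sp. PCC 7120	Filamentous Heterocystous Freshwater	5366	7	0.13	2	43
Anabaena variabilis ATCC 29413	Filamentous Heterocystous Soil	5043	9	0.18	2	64
Gloeobacter violaceus PCC 7421	Unicellular Rock	4430	4	0.09	0	56
Synechococcus sp. JA-2-3B'a(2-13)	Unicellular Hot spring	2862	1	0.03	1	0
Synechococcus sp. JA-3-3Ab	Unicellular Hot spring	2760	1	0.04	1	0
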