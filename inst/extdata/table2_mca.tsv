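gene_id	strain	family	sites	domains	annotation
641253645	Acaryochloris marina MBIC 11017	cbMCa-other	H-Y C-G		Protease (caspase) p20 domain containing protein
641252580	Acaryochloris marina MBIC 11017	cbMCb		NACHT, WD40(13)	WD-40 repeat protein
641249149	Acaryochloris marina MBIC 11017	cbMCb		WD40(7)	WD-repeat protein
641257459	Acaryochloris marina MBIC 11017	cbMCb		Pentapeptide(4)	Peptidase C14, caspase catalytic subunit p20
641250651	Acaryochloris marina MBIC 11017	cbMCb		GUN4	GUN4-like family protein
641254504	Acaryochloris marina MBIC 11017	cbMCa-TM			WD-40 repeat protein
641249463	Acaryochloris marina MBIC 11017	cbMCb		DUF323	Hypothetical protein
641257535	Acaryochloris marina MBIC 11017	cbMCb		DEXDc, HELICc	Dead/death box helicase domain protein
637717727	Anabaena variabilis ATCC 29413	cbMCa-other	H-Y C-S		Peptidase C14, caspase catalytic subunit p20
637718597	Anabaena variabilis ATCC 29413	cbMCa-other			Peptidase C14, caspase catalytic subunit p20
637715366	Anabaena variabilis ATCC 29413	cbMCb		WD40(14)	Peptidase C14, caspase catalytic subunit p20
637719457	Anabaena variabilis ATCC 29413	cbMCa-other			Peptidase C14, caspase catalytic subunit p20
637717526	Anabaena variabilis ATCC 29413	cbMCb		WD40(14)	Peptidase C14, caspase catalytic subunit p20
637717527	Anabaena variabilis ATCC 29413	cbMCb		WD40(8)	Peptidase C14, caspase catalytic subunit p20
637718424	Anabaena variabilis ATCC 29413	cbMCb		WD40(14)	Peptidase C14, caspase catalytic subunit p20
637718423	Anabaena variabilis ATCC 29413	cbMCb		WD40(14)	Peptidase C14, caspase catalytic subunit p20
637718962	Anabaena variabilis ATCC 29413	cbMCa-TM	H-Y C-N		Peptidase C14, caspase catalytic subunit p20
641679166	Cyanothece sp. ATCC 51142	cbMCa-other	H-Y C-S		Putative peptidase C14, caspase catalytic
641676675	Cyanothece sp. ATCC 51142	cbMCb		NACHT, WD40(15)	WD-40 repeat protein
641678142	Cyanothece sp. ATCC 51142	cbMCa-other	H-Y C-Q		Putative peptidase C14, caspase catalytic
637459639	Gloeobacter violaceus PCC 7421	cbMCb		WD40(14)	WD-repeat protein
637458101	Gloeobacter violaceus PCC 7421	cbMCb		WD40(14)	WD-40 repeat protein
637459020	Gloeobacter violaceus PCC 7421	cbMCb		WD40(14)	WD-40 repeat protein
637461074	Gloeobacter violaceus PCC 7421	cbMCb		WD40(14)	WD-40 repeat protein
641536480	Microcystis aeruginosa NIES-843	cbMCa-other			Peptidase C14, caspase catalytic subunit p20
641535722	Microcystis aeruginosa NIES-843	cbMCa-other	H-Y C-S		Peptidase C14, caspase catalytic subunit p20
638389336	Nostoc punctiforme PCC 73102	cbMCa-other			Hypothetical protein
638391264	Nostoc punctiforme PCC 73102	cbMCa-other			Hypothetical protein
638390474	Nostoc punctiforme PCC 73102	cbMCa-other	H-Y C-S		Hypothetical protein
638392408	Nostoc punctiforme PCC 73102	cbMCa-TM			Hypothetical protein
638386606	Nostoc punctiforme PCC 73102	cbMCb		ANF-receptor	ABC-type branched-chain amino acid transport systems, periplasmic component
638389051	Nostoc punctiforme PCC 73102	cbMCb		DUF323	Chromosome segregation ATPases
638388760	Nostoc punctiforme PCC 73102	cbMCb		Pentapeptide(3)	Uncharacterized protein containing caspase domain
638390427	Nostoc punctiforme PCC 73102	cbMCa-TM	H-Y C-N		Uncharacterized protein containing caspase domain
638392333	Nostoc punctiforme PCC 73102	cbMCb		GUN4	Uncharacterized protein containing caspase domain
637235546	Nostoc sp. PCC 7120	cbMCa-other	H-Y C-S		Hypothetical protein
637230642	Nostoc sp. PCC 7120	cbMCb		WD40(14)	WD-40 repeat protein
637230643	Nostoc sp. PCC 7120	cbMCb		WD40(14)	WD-40 repeat protein
637232504	Nostoc sp. PCC 7120	cbMCb		WD40(14)	WD-40 repeat protein
637235425	Nostoc sp. PCC 7120	cbMCa-I			Hypothetical protein
637233614	Nostoc sp. PCC 7120	cbMCb		DUF323	Hypothetical protein
637234068	Nostoc sp. PCC 7120	cbMCa-TM	H-Y C-N		Hypothetical protein
637616879	Synechococcus elongatus PCC 6301	cbMCa-other	C-G		Hypothetical protein
637798702	Synechococcus elongatus PCC 7942	cbMCa-other	C-G		Hypothetical protein
637875026	Synechococcus sp. JA-2-3B'a(2-13)	cbMCa-other	H-Y C-G		Peptidase, C14 family
637872245	Synechococcus sp. JA-3-3Ab	cbMCa-other	H-Y C-G		ICE-like protease (caspase) p20 domain protein
641610111	Synechococcus sp. PCC 7002	cbMCa-other	H-Y C-S		ICE-like protease (caspase) p20 domain protein
637011435	Synechocystis sp. PCC 6803	cbMCa-other	H-Y C-G		Hypothetical protein
638107693	Trichodesmium erythraeum IMS 101	cbMCa-other	H-Y C-S		Peptidase C14, caspase catalytic subunit p20
638106962	Trichodesmium erythraeum IMS 101	cbMCb		EZ-HEAT(15)	Peptidase C14, caspase catalytic subunit p20
638107555	Trichodesmium erythraeum IMS 101	cbMCb		WD40(14)	Peptidase C14, caspase catalytic subunit p20
638109494	Trichodesmium erythraeum IMS 101	cbMCb		WD40(15)	WD-40 repeat
638108799	Trichodesmium erythraeum IMS 101	cbMCb		WD40(15)	WD-40 repeat
638107819	Trichodesmium erythraeum IMS 101	cbMCa-C			Peptidase C14, caspase catalytic subunit p20
638107188	Trichodesmium erythraeum IMS 101	cbMCb		DUF323	Protein of unknown function DUF 323
638107169	Trichodesmium erythraeum IMS 101	cbMCa-other			Peptidase C14, caspase catalytic subunit p20
638107752	Trichodesmium erythraeum IMS 101	cbMCb		DUF323	Protein of unknown function DUF 323
638105709	Trichodesmium erythraeum IMS 101	cbMCb		CHASE2	Putative Chase2 sensor protein
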