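drug_id	source	properties
D001	LITERATURE	antineoplastic
D002	DATABASE	antifungal
D003	DATABASE	anti-inflammatory
D004	DATABASE	anti-inflammatory
D005	LITERATURE	antifungal
D006	DATABASE	antifungal
D007	DATABASE	anti-inflammatory
D008	DATABASE	antifungal
D009	DATABASE	anti-inflammatory
D010	DATABASE	antineoplastic
D011	DATABASE	antifungal
D012	DATABASE	anti-inflammatory
D013	DATABASE	antineoplastic
D014	DATABASE	antifungal
D015	LITERATURE	anti-inflammatory
D016	DATABASE	antineoplastic
D017	DATABASE	antifungal
D018	DATABASE	antineoplastic
D019	LITERATURE	antineoplastic
D020	DATABASE	antifungal
D021	DATABASE	antifungal
D022	DATABASE	antineoplastic
D023	DATABASE	antifungal
D024	DATABASE	anti-inflammatory
D025	LITERATURE	antineoplastic
D026	DATABASE	antifungal
D027	DATABASE	anti-inflammatory
D028	LITERATURE	antineoplastic
D029	DATABASE	antineoplastic
D030	LITERATURE	anti-inflammatory
D031	DATABASE	antineoplastic
D032	DATABASE	antifungal
D033	DATABASE	anti-inflammatory
D034	DATABASE	antineoplastic
D035	DATABASE	antineoplastic
D036	DATABASE	anti-inflammatory
D037	DATABASE	antineoplastic
D038	DATABASE	antifungal
D039	DATABASE	anti-inflammatory
D040	DATABASE	antineoplastic
D041	DATABASE	anti-inflammatory
D042	LITERATURE	anti-inflammatory
D043	DATABASE	antineoplastic
D044	LITERATURE	antifungal
D045	LITERATURE	anti-inflammatory
D046	DATABASE	antineoplastic
D047	DATABASE	antifungal
D048	DATABASE	anti-inflammatory
D049	LITERATURE	antineoplastic
D050	DATABASE	antifungal
D051	DATABASE	anti-inflammatory
D052	LITERATURE	antifungal
D053	LITERATURE	antifungal
D054	DATABASE	anti-inflammatory
D055	DATABASE	antineoplastic
D056	LITERATURE	antifungal
D057	DATABASE	anti-inflammatory
D058	LITERATURE	antineoplastic
D059	DATABASE	antifungal
D060	LITERATURE	anti-inflammatory
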