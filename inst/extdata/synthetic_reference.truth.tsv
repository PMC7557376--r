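drug_id	block	property
D001	1	antineoplastic
D002	2	antifungal
D003	3	anti-inflammatory
D004	1	antineoplastic
D005	2	antifungal
D006	3	anti-inflammatory
D007	1	antineoplastic
D008	2	antifungal
D009	3	anti-inflammatory
D010	1	antineoplastic
D011	2	antifungal
D012	3	anti-inflammatory
D013	1	antineoplastic
D014	2	antifungal
D015	3	anti-inflammatory
D016	1	antineoplastic
D017	2	antifungal
D018	3	anti-inflammatory
D019	1	antineoplastic
D020	2	antifungal
D021	3	anti-inflammatory
D022	1	antineoplastic
D023	2	antifungal
D024	3	anti-inflammatory
D025	1	antineoplastic
D026	2	antifungal
D027	3	anti-inflammatory
D028	1	antineoplastic
D029	2	antifungal
D030	3	anti-inflammatory
D031	1	antineoplastic
D032	2	antifungal
D033	3	anti-inflammatory
D034	1	antineoplastic
D035	2	antifungal
D036	3	anti-inflammatory
D037	1	antineoplastic
D038	2	antifungal
D039	3	anti-inflammatory
D040	1	antineoplastic
D041	2	antifungal
D042	3	anti-inflammatory
D043	1	antineoplastic
D044	2	antifungal
D045	3	anti-inflammatory
D046	1	antineoplastic
D047	2	antifungal
D048	3	anti-inflammatory
D049	1	antineoplastic
D050	2	antifungal
D051	3	anti-inflammatory
D052	1	antineoplastic
D053	2	antifungal
D054	3	anti-inflammatory
D055	1	antineoplastic
D056	2	antifungal
D057	3	anti-inflammatory
D058	1	antineoplastic
D059	2	antifungal
D060	3	anti-inflammatory
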