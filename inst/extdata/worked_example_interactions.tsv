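drug_id	drug_name	target_id	target_name	action
Drug1	Drug1	T1	Target1	antagonist
Drug1	Drug1	T2	Target2	agonist
Drug1	Drug1	T3	Target3	antagonist
Drug2	Drug2	T1	Target1	antagonist
Drug2	Drug2	T2	Target2	agonist
Drug2	Drug2	T3	Target3	antagonist
Drug4	Drug4	T1	Target1	antagonist
Drug4	Drug4	T2	Target2	agonist
Drug4	Drug4	T3	Target3	agonist
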