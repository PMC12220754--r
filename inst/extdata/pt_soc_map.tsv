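pt	pt_code	soc	soc_code
Nightmare	10029412	Psychiatric disorders	10037175
Aggression	10001488	Psychiatric disorders	10037175
Anxiety	10002855	Psychiatric disorders	10037175
Depression	10012378	Psychiatric disorders	10037175
Insomnia	10022437	Psychiatric disorders	10037175
Sleep terror	10040984	Psychiatric disorders	10037175
Suicidal ideation	10042458	Psychiatric disorders	10037175
Abnormal behaviour	10061422	Psychiatric disorders	10037175
Irritability	10022998	Psychiatric disorders	10037175
Obsessive-compulsive disorder	10029898	Psychiatric disorders	10037175
Tic	10043833	Psychiatric disorders	10037175
Hallucination	10019063	Psychiatric disorders	10037175
Agitation	10001497	Psychiatric disorders	10037175
Somnambulism	10041347	Psychiatric disorders	10037175
Headache	10019211	Nervous system disorders	10029205
Dizziness	10013573	Nervous system disorders	10029205
Somnolence	10041349	Nervous system disorders	10029205
Tremor	10044565	Nervous system disorders	10029205
Paraesthesia	10033775	Nervous system disorders	10029205
Migraine	10027599	Nervous system disorders	10029205
Seizure	10039906	Nervous system disorders	10029205
Memory impairment	10027175	Nervous system disorders	10029205
Dyspnoea	10013968	Respiratory, thoracic and mediastinal disorders	10038738
Cough	10011224	Respiratory, thoracic and mediastinal disorders	10038738
Asthma	10003553	Respiratory, thoracic and mediastinal disorders	10038738
Wheezing	10047924	Respiratory, thoracic and mediastinal disorders	10038738
Epistaxis	10015090	Respiratory, thoracic and mediastinal disorders	10038738
Nasal congestion	10028735	Respiratory, thoracic and mediastinal disorders	10038738
Pulmonary eosinophilia	10037423	Respiratory, thoracic and mediastinal disorders	10038738
Rhinitis allergic	10039085	Respiratory, thoracic and mediastinal disorders	10038738
Nausea	10028813	Gastrointestinal disorders	10017947
Vomiting	10047700	Gastrointestinal disorders	10017947
Diarrhoea	10012735	Gastrointestinal disorders	10017947
Abdominal pain	10000081	Gastrointestinal disorders	10017947
Dry mouth	10013781	Gastrointestinal disorders	10017947
Dyspepsia	10013946	Gastrointestinal disorders	10017947
Drug ineffective	10013709	General disorders and administration site conditions	10018065
Fatigue	10016256	General disorders and administration site conditions	10018065
Pyrexia	10037660	General disorders and administration site conditions	10018065
Malaise	10025482	General disorders and administration site conditions	10018065
Chest pain	10008479	General disorders and administration site conditions	10018065
Condition aggravated	10010264	General disorders and administration site conditions	10018065
Anaphylactic reaction	10002198	Immune system disorders	10021428
Hypersensitivity	10020751	Immune system disorders	10021428
Eosinophilic granulomatosis with polyangiitis	10078117	Immune system disorders	10021428
Drug hypersensitivity	10013700	Immune system disorders	10021428
Rash	10037844	Skin and subcutaneous tissue disorders	10040785
Pruritus	10037087	Skin and subcutaneous tissue disorders	10040785
Urticaria	10046735	Skin and subcutaneous tissue disorders	10040785
Angioedema	10002424	Skin and subcutaneous tissue disorders	10040785
Alopecia	10001760	Skin and subcutaneous tissue disorders	10040785
Educational problem	10014191	Social circumstances	10041244
Physical abuse	10063458	Social circumstances	10041244
Arthralgia	10003239	Musculoskeletal and connective tissue disorders	10028395
Myalgia	10028411	Musculoskeletal and connective tissue disorders	10028395
Muscle spasms	10028334	Musculoskeletal and connective tissue disorders	10028395
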