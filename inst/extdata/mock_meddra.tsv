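pt_code	pt_name	hlt_code	hlt_name	soc_code	soc_name	smq_memberships
10000001	aggression	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000002	behavioural disturbance	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000003	anger reaction	HLT10002	impulse control disorders	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000004	hostility	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000005	symptom related to violence	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000006	homicidal ideation	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000007	antisocial behaviour	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000008	intermittent explosive disorder	HLT10002	impulse control disorders	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000009	physical abuse	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000010	sexual abuse	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000011	physical assault	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000012	conduct disorder	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000013	belligerence	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000014	abusive behaviour towards a child	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000015	homicide	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000016	incest	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000017	psychopathic personality	HLT10003	personality disorders and disturbances	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000018	antisocial personality disorder	HLT10003	personality disorders and disturbances	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000019	borderline personality disorder	HLT10003	personality disorders and disturbances	SOC10001	psychiatric disorders	hostility_aggression:narrow
10000020	abuse of an elderly person	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:broad
10000021	spousal abuse	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:broad
10000022	psychological abuse	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:broad
10000023	verbal abusive behaviour	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:broad
10000024	delinquency	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:broad
10000025	agitated depression	HLT10004	depressive disorders	SOC10001	psychiatric disorders	hostility_aggression:broad
10000026	shouting	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:broad
10000027	gunshot wound	HLT10005	site specific injuries	SOC10002	injury, poisoning and procedural complications	hostility_aggression:broad
10000028	stab wound	HLT10005	site specific injuries	SOC10002	injury, poisoning and procedural complications	hostility_aggression:broad
10000029	bite	HLT10005	site specific injuries	SOC10002	injury, poisoning and procedural complications	hostility_aggression:broad
10000030	human bite	HLT10005	site specific injuries	SOC10002	injury, poisoning and procedural complications	hostility_aggression:broad
10000031	paraphilia	HLT10006	sexual dysfunctions, disturbances and gender identity disorders	SOC10001	psychiatric disorders	hostility_aggression:broad
10000032	paranoia	HLT10007	psychotic disorders	SOC10001	psychiatric disorders	hostility_aggression:broad
10000033	paedophilia	HLT10006	sexual dysfunctions, disturbances and gender identity disorders	SOC10001	psychiatric disorders	hostility_aggression:broad
10000034	fighting at school	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:broad
10000035	pyromania	HLT10002	impulse control disorders	SOC10001	psychiatric disorders	hostility_aggression:broad
10000036	robbery	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:broad
10000037	sadism	HLT10006	sexual dysfunctions, disturbances and gender identity disorders	SOC10001	psychiatric disorders	hostility_aggression:broad
10000038	activation syndrome	HLT10002	impulse control disorders	SOC10001	psychiatric disorders	hostility_aggression:broad
10000039	bipolar disorder I	HLT10008	manic and bipolar mood disorders and disturbances	SOC10001	psychiatric disorders	hostility_aggression:broad
10000040	bipolar disorder II	HLT10008	manic and bipolar mood disorders and disturbances	SOC10001	psychiatric disorders	hostility_aggression:broad
10000041	bipolar disorder	HLT10008	manic and bipolar mood disorders and disturbances	SOC10001	psychiatric disorders	hostility_aggression:broad
10000042	personality disorder	HLT10003	personality disorders and disturbances	SOC10001	psychiatric disorders	hostility_aggression:broad
10000043	impulse control disorder	HLT10002	impulse control disorders	SOC10001	psychiatric disorders	hostility_aggression:broad
10000044	delusional disorder, persecution type	HLT10007	psychotic disorders	SOC10001	psychiatric disorders	hostility_aggression:broad
10000045	delusional disorder, jealous type	HLT10007	psychotic disorders	SOC10001	psychiatric disorders	hostility_aggression:broad
10000046	oppositional defiant disorder	HLT10001	behavioural or socialisation disturbances	SOC10001	psychiatric disorders	hostility_aggression:broad
10000047	paranoid personality disorder	HLT10003	personality disorders and disturbances	SOC10001	psychiatric disorders	hostility_aggression:broad
10000048	nausea	HLT10009	nausea and vomiting symptoms	SOC10003	gastrointestinal disorders	
10000049	vomiting	HLT10009	nausea and vomiting symptoms	SOC10003	gastrointestinal disorders	
10000050	diarrhoea	HLT10010	diarrhoea (excl infective)	SOC10003	gastrointestinal disorders	
10000051	headache	HLT10011	headaches	SOC10004	nervous system disorders	
10000052	dizziness	HLT10012	neurological signs and symptoms	SOC10004	nervous system disorders	
10000053	somnolence	HLT10013	disturbances in consciousness	SOC10004	nervous system disorders	
10000054	rash	HLT10014	rashes, eruptions and exanthems	SOC10005	skin and subcutaneous tissue disorders	
10000055	pruritus	HLT10015	pruritus	SOC10005	skin and subcutaneous tissue disorders	
10000056	pyrexia	HLT10016	febrile disorders	SOC10006	general disorders and administration site conditions	
10000057	fatigue	HLT10017	asthenic conditions	SOC10006	general disorders and administration site conditions	
10000058	insomnia	HLT10018	sleep disturbances	SOC10001	psychiatric disorders	
10000059	hepatotoxicity	HLT10019	hepatocellular damage and hepatitis	SOC10007	hepatobiliary disorders	
10000060	anaemia	HLT10020	anaemias	SOC10008	blood and lymphatic system disorders	
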