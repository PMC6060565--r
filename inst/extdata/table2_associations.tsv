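node	mutual_information	normalized_mi_pct	relative_mi_pct	pearson_r	df	p_value_pct
HEALTH	0.0238	2.3789	12.0116	0.19	4	0.0000
AGE	0.0219	2.1912	11.0641	0.18	2	0.0000
EMPSTATWKYR	0.0214	2.1365	10.7878	0.16	3	0.0000
HYPERTENEV	0.0183	1.8331	9.2558	0.17	1	0.0000
CHEARTDIEV	0.0127	1.2748	6.4370	0.18	1	0.0000
HEARTATTEV	0.0125	1.2502	6.3125	0.19	1	0.0000
MARSTAT	0.0090	0.9033	4.5610	-0.04	4	0.0000
HEARTCONEV	0.0086	0.8569	4.3267	0.14	1	0.0000
DIABETICEV	0.0083	0.8287	4.1841	0.11	2	0.0000
VIG10DMIN	0.0069	0.6854	3.4607	-0.07	3	0.0000
ANGIPECEV	0.0064	0.6388	3.2254	0.13	1	0.0000
ALCSTAT1	0.0061	0.6064	3.0617	-0.06	2	0.0000
ALCSTAT2	0.0060	0.6005	3.0319	-0.01	6	0.0000
INCFAM97ON2	0.0054	0.5423	2.7383	-0.08	2	0.0000
KIDNEYWKYR	0.0045	0.4503	2.2738	0.11	1	0.0000
HRSLEEP	0.0038	0.3799	1.9183	0.03	2	0.0000
EMPHYSEMEV	0.0037	0.3665	1.8504	0.09	1	0.0000
EDUCREC1	0.0031	0.3112	1.5715	-0.06	3	0.0000
MOD10DMIN	0.0031	0.3111	1.5709	-0.04	3	0.0000
USUALPL	0.0027	0.2666	1.3460	0.05	2	0.0000
EMODISTRESS	0.0016	0.1649	0.8328	0.06	1	0.0000
WORKEV	0.0016	0.1617	0.8166	0.04	1	0.0000
POORYN	0.0011	0.1124	0.5677	0.04	1	0.0000
SMOKEV	0.0011	0.1122	0.5663	0.04	1	0.0000
MOD10FWK	0.0009	0.0854	0.4312	0.02	6	0.0000
LIVERCONYR	0.0007	0.0722	0.3646	0.04	1	0.0000
RACEA	0.0007	0.0660	0.3330	-0.01	3	0.0000
HISPETH	0.0006	0.0631	0.3186	-0.03	1	0.0000
VIG10FWK	0.0005	0.0488	0.2464	0.01	6	0.0000
HEIGHT	0.0005	0.0482	0.2432	-0.02	3	0.0000
BMICALC	0.0005	0.0463	0.2337	0.02	3	0.0000
REGION	0.0004	0.0354	0.1788	-0.01	3	0.0000
WEIGHT	0.0001	0.0058	0.0291	0.01	3	0.0351
SEX	0.0000	0.0041	0.0209	0.01	1	0.0267
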