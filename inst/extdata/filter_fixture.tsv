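SAMPLING EVENT IDENTIFIER	SCIENTIFIC NAME	LATITUDE	LONGITUDE	COUNTY	OBSERVATION DATE	TIME OBSERVATIONS STARTED	DURATION MINUTES	EFFORT DISTANCE KM	EFFORT AREA HA	ALL SPECIES REPORTED	PROTOCOL TYPE
F1	Species_01	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		1	Traveling
F1	Species_02	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		1	Traveling
F1	Species_03	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		1	Traveling
F1	Species_04	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		1	Traveling
F1	Species_05	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		1	Traveling
F1	Species_06	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		1	Traveling
F2	Species_01	-33.8	150.9	County_1	2018-06-10	08:00:00	60			1	Stationary
F2	Species_02	-33.8	150.9	County_1	2018-06-10	08:00:00	60			1	Stationary
F2	Species_03	-33.8	150.9	County_1	2018-06-10	08:00:00	60			1	Stationary
F2	Species_04	-33.8	150.9	County_1	2018-06-10	08:00:00	60			1	Stationary
F2	Species_05	-33.8	150.9	County_1	2018-06-10	08:00:00	60			1	Stationary
F3	Species_01	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		0	Traveling
F3	Species_02	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		0	Traveling
F3	Species_03	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		0	Traveling
F3	Species_04	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		0	Traveling
F3	Species_05	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		0	Traveling
F3	Species_06	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		0	Traveling
F4	Species_01	-33.8	150.9	County_1	2018-06-10	08:00:00	4	2		1	Traveling
F4	Species_02	-33.8	150.9	County_1	2018-06-10	08:00:00	4	2		1	Traveling
F4	Species_03	-33.8	150.9	County_1	2018-06-10	08:00:00	4	2		1	Traveling
F4	Species_04	-33.8	150.9	County_1	2018-06-10	08:00:00	4	2		1	Traveling
F4	Species_05	-33.8	150.9	County_1	2018-06-10	08:00:00	4	2		1	Traveling
F4	Species_06	-33.8	150.9	County_1	2018-06-10	08:00:00	4	2		1	Traveling
F5	Species_01	-33.8	150.9	County_1	2018-06-10	08:00:00	60	6		1	Traveling
F5	Species_02	-33.8	150.9	County_1	2018-06-10	08:00:00	60	6		1	Traveling
F5	Species_03	-33.8	150.9	County_1	2018-06-10	08:00:00	60	6		1	Traveling
F5	Species_04	-33.8	150.9	County_1	2018-06-10	08:00:00	60	6		1	Traveling
F5	Species_05	-33.8	150.9	County_1	2018-06-10	08:00:00	60	6		1	Traveling
F5	Species_06	-33.8	150.9	County_1	2018-06-10	08:00:00	60	6		1	Traveling
F6	Species_01	-33.8	150.9	County_1	2018-06-10	08:00:00	60		300	1	Area
F6	Species_02	-33.8	150.9	County_1	2018-06-10	08:00:00	60		300	1	Area
F6	Species_03	-33.8	150.9	County_1	2018-06-10	08:00:00	60		300	1	Area
F6	Species_04	-33.8	150.9	County_1	2018-06-10	08:00:00	60		300	1	Area
F6	Species_05	-33.8	150.9	County_1	2018-06-10	08:00:00	60		300	1	Area
F6	Species_06	-33.8	150.9	County_1	2018-06-10	08:00:00	60		300	1	Area
F6	Species_07	-33.8	150.9	County_1	2018-06-10	08:00:00	60		300	1	Area
F7	Species_01	-33.8	150.9	County_1	2018-06-10	08:00:00	239	2		1	Traveling
F7	Species_02	-33.8	150.9	County_1	2018-06-10	08:00:00	239	2		1	Traveling
F7	Species_03	-33.8	150.9	County_1	2018-06-10	08:00:00	239	2		1	Traveling
F7	Species_04	-33.8	150.9	County_1	2018-06-10	08:00:00	239	2		1	Traveling
F7	Species_05	-33.8	150.9	County_1	2018-06-10	08:00:00	239	2		1	Traveling
F8	Species_01	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		1	Traveling
F8	Species_02	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		1	Traveling
F8	Species_03	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		1	Traveling
F8	Species_04	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		1	Traveling
F8	Species_05	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		1	Traveling
F8	Species_06	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		1	Traveling
F8	Species_07	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		1	Traveling
F8	Species_08	-33.8	150.9	County_1	2018-06-10	08:00:00	60	2		1	Traveling
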