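tip_label	tip_age	ghost	host	regime
Archicebus_achilles	55	1	strepsirrhine	a
Eosimias_sinensis	45	1	anthropoid	a
Karanisia_clarki	37	1	strepsirrhine	a
Komba_robustus	20	1	strepsirrhine	a
Carlocebus_carmenensis	17.5	1	platyrrhine	a
Nycticeboides_simpsoni	8	1	strepsirrhine	a
Branisella_boliviana	26	1	platyrrhine	a
Epipliopithecus_vindobonensis	15	1	cercopithecoid	h
Victoriapithecus_macinnesi	15	1.5	cercopithecoid	h
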