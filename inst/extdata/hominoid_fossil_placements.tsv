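tip_label	tip_age	attach_child	ghost
Proconsul_africanus	22.5	mrca:Homo_sapiens+Hylobates_lar	1
Proconsul_major	22.5	Proconsul_africanus	0.5
Ekembo_heseloni	18.5	mrca:Homo_sapiens+Hylobates_lar	1.2
Ekembo_nyanzae	18.5	Ekembo_heseloni	0.6
Pliobates_cataloniae	11.6	mrca:Hylobates_lar+Symphalangus_syndactylus	1
Dryopithecus_fontani	11.8	mrca:Homo_sapiens+Gorilla_gorilla	1
Hispanopithecus_laietanus	9.6	mrca:Homo_sapiens+Gorilla_gorilla	1
Sivapithecus_indicus	12.7	mrca:Pongo_abelii+Pongo_pygmaeus	1
Orrorin_tugenensis	6	Homo_sapiens	1
Ardipithecus_ramidus	4.4	Homo_sapiens	1
Australopithecus_anamensis	4.17	Homo_sapiens	1
Australopithecus_afarensis	3.77	Homo_sapiens	1
Australopithecus_africanus	3.03	Homo_sapiens	1
Homo_habilis	2.33	Homo_sapiens	1
Paranthropus_boisei	2.3	Homo_sapiens	1
Homo_floresiensis	0.1	Homo_sapiens	3
Paranthropus_robustus	2	Homo_sapiens	1
Australopithecus_sediba	1.95	Homo_sapiens	1
Homo_erectus	1.9	Homo_sapiens	1
Homo_heidelbergensis	0.61	Homo_sapiens	1
Homo_neanderthalensis	0.13	Homo_sapiens	1
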