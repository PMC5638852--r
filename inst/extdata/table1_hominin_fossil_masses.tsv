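species	tip_label	mass_kg	mass_small_kg	first_appearance_ma	n	family
Orrorin tugenensis	Orrorin_tugenensis	46.5	35.8	6.00	2	Hominidae
Ar. ramidus	Ardipithecus_ramidus	50.8	32.1	4.40	1	Hominidae
Au. anamensis	Australopithecus_anamensis	46.30	NA	4.17	1	Hominidae
Au. afarensis	Australopithecus_afarensis	39.10	NA	3.77	12	Hominidae
Au. africanus	Australopithecus_africanus	30.50	NA	3.03	5	Hominidae
Au. sediba	Australopithecus_sediba	26.70	NA	1.95	2	Hominidae
P. boisei	Paranthropus_boisei	35.30	NA	2.30	8	Hominidae
P. robustus	Paranthropus_robustus	30.10	NA	2.00	4	Hominidae
H. habilis	Homo_habilis	32.60	NA	2.33	2	Hominidae
H. erectus	Homo_erectus	51.00	NA	1.90	7	Hominidae
H. floresiensis	Homo_floresiensis	27.50	NA	0.10	1	Hominidae
H. heidelbergensis	Homo_heidelbergensis	69.10	NA	0.61	5	Hominidae
H. neanderthalensis	Homo_neanderthalensis	75.40	NA	0.13	14	Hominidae
H. sapiens	Homo_sapiens	58.20	NA	0.20	51	Hominidae
Proconsul africanus	Proconsul_africanus	35.00	NA	22.50	NA	Proconsulidae
Proconsul major	Proconsul_major	75.00	NA	22.50	NA	Proconsulidae
Ekembo heseloni	Ekembo_heseloni	15.00	NA	18.50	NA	Proconsulidae
Ekembo nyanzae	Ekembo_nyanzae	35.00	NA	18.50	NA	Proconsulidae
Dryopithecus fontani	Dryopithecus_fontani	43.60	NA	11.80	1	Hominidae
Hispanopithecus laietanus	Hispanopithecus_laietanus	32.00	NA	9.60	2	Hominidae
Sivapithecus indicus	Sivapithecus_indicus	30.50	NA	12.70	6	Hominidae
Pliobates cataloniae	Pliobates_cataloniae	4.50	NA	11.60	1	Pliobatidae
Pan troglodytes	Pan_troglodytes	45.00	NA	2.33	60	Hominidae
Pan paniscus	Pan_paniscus	39.10	NA	2.33	13	Hominidae
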