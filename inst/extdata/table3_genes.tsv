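# Representative co-localized gene locus per QTL (1-based inclusive).
# corrected = yes marks end coordinates whose leading digits were truncated
# in the printed source table and have been editorially restored.
gene_id	qtl_id	chrom	start	end	corrected
Sb01g012195	QYLD1.2	Chr 1	11188494	11188718	no
Sb01g012230	QYLD1.3	Chr 1	11244033	11246659	no
Sb01g036220	QSDW1	Chr 1	59863444	59868128	no
Sb01g030510	QGI-1	Chr 1	52963286	52964344	no
Sb02g027900	QYLD2.1	Chr 2	63173883	63174687	yes
Sb02g037700	QRDW1_2	Chr 2	71999473	72002734	no
Sb03g040510	qGI-3	Chr 3	68140707	68142336	no
Sb04g006830	QSPAD4.1	Chr 4	6853756	6858575	no
Sb04g019670	QYLD4.1	Chr 4	45942011	45943013	no
Sb04g034665	qFv/Fm4.1	Chr 4	64501979	64504340	yes
Sb04g027660	qGI-4	Chr 4	57562353	57564270	no
Sb05g007450	QRA1_5	Chr 5	13463573	13469204	no
Sb06g001033	qFT6.1	Chr 6	1479485	1483300	no
Sb06g020970	QYLD6.1	Chr 6	50361776	50364655	yes
Sb06g025130	qGI-6	Chr 6	54128281	54131608	no
Sb07g024070	qGI-7	Chr 7	59081442	59086488	no
Sb08g005781	QRA1_8	Chr 8	8160471	8161062	no
Sb08g017820	QTLA1_8	Chr 8	47829763	47830809	no
Sb08g018270	QRDW1_8	Chr 8	48273154	48279810	yes
Sb09g004180	qFT9.1	Chr 9	4910985	4919916	no
Sb09g028980	qGI-9	Chr 9	57747092	57747957	no
Sb10g027700	QRA1_10	Chr 10	57507083	57508898	no
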