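# Sorghum drought-tolerance QTL regions with the number of co-localized
# candidate genes found per QTL (column `total`). Coordinates are 1-based
# inclusive.
qtl_id	trait	chrom	start	end	ref	total
QYLD1.2	grain yield	Chr 1	11145830	12704841	ref048	1
QYLD1.3	grain yield	Chr 1	11203256	21602500	ref048	8
QSDW1	shoot dry weight	Chr 1	59861427	64432960	ref047	6
QGI-1	seed dormancy	Chr 1	52962744	55721536	ref049	13
QYLD2.1	grain yield	Chr 2	63084956	63712593	ref048	6
QRDW1_2	root dry weight	Chr 2	71995008	77001005	ref047	8
qGI-3	seed dormancy	Chr 3	68132731	72423918	ref049	9
QSPAD4.1	stay-green	Chr 4	6803028	10119054	ref048	26
QYLD4.1	grain yield	Chr 4	45937548	62339532	ref048	10
qFv/Fm4.1	stay-green	Chr 4	64497114	65560043	ref048	18
qGI-4	seed dormancy	Chr 4	57546281	58537697	ref049	8
QRA1_5	nodal root angle	Chr 5	13413924	45779999	ref047	6
qFT6.1	flowering time	Chr 6	1402697	40763291	ref048	7
QYLD6.1	grain yield	Chr 6	50360463	52945337	ref048	3
qGI-6	seed dormancy	Chr 6	54128269	59786660	ref049	8
qGI-7	seed dormancy	Chr 7	59065206	60579009	ref049	7
QRA1_8	nodal root angle	Chr 8	8067699	41591844	ref047	3
QTLA1_8	total leaf area	Chr 8	47817803	48269890	ref047	3
QRDW1_8	root dry weight	Chr 8	48269890	50970340	ref047	4
qFT9.1	flowering time	Chr 9	4719436	7580762	ref048	5
qGI-9	seed dormancy	Chr 9	57746020	58246041	ref049	3
QRA1_10	nodal root angle	Chr 10	57494967	58573866	ref048	7
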