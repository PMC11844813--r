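##fileformat=VCFv4.2
##contig=<ID=chr01>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	QTP-test4	QTP-test5	QTP-test8	NC-test9	NC-test12	NE-test6	QTP-test1	NW-test1
chr01	500	ksnp01	T	A	.	PASS	.	GT	0/1	./.	0/1	0/0	0/1	0/1	0/1	0/1
chr01	900	ksnp02	A	T	.	PASS	.	GT	0/0	./.	0/0	0/0	0/0	0/0	0/0	0/0
chr01	1300	ksnp03	G	T	.	PASS	.	GT	0/0	./.	0/0	0/0	0/0	0/0	0/0	0/0
chr01	1700	ksnp04	A	C	.	PASS	.	GT	0/1	./.	0/1	0/1	0/1	0/1	0/0	0/0
chr01	2100	ksnp05	A	T	.	PASS	.	GT	1/1	./.	1/1	1/1	1/1	1/1	1/1	1/1
chr01	2500	ksnp06	T	A	.	PASS	.	GT	0/0	./.	0/0	0/0	0/0	0/0	0/0	0/0
chr01	2900	ksnp07	A	G	.	PASS	.	GT	1/1	./.	1/1	1/1	1/1	1/1	1/1	1/1
chr01	3300	ksnp08	G	T	.	PASS	.	GT	1/1	./.	1/1	1/1	1/1	1/1	1/1	0/1
chr01	3700	ksnp09	G	C	.	PASS	.	GT	1/1	./.	1/1	1/1	1/1	1/1	1/1	1/1
chr01	4100	ksnp10	C	G	.	PASS	.	GT	0/0	./.	0/0	0/0	0/0	0/0	0/0	0/0
chr01	4500	ksnp11	T	G	.	PASS	.	GT	1/1	./.	1/1	1/1	1/1	1/1	1/1	1/1
chr01	4900	ksnp12	T	A	.	PASS	.	GT	1/1	./.	1/1	1/1	1/1	1/1	1/1	0/1
chr01	5300	ksnp13	T	C	.	PASS	.	GT	1/1	./.	1/1	1/1	1/1	1/1	1/1	1/1
chr01	5700	ksnp14	A	G	.	PASS	.	GT	1/1	./.	1/1	1/1	1/1	1/1	1/1	1/1
chr01	6100	ksnp15	T	C	.	PASS	.	GT	0/0	./.	0/0	0/0	0/0	0/0	0/0	0/0
chr01	6500	ksnp16	T	G	.	PASS	.	GT	0/1	./.	0/1	0/1	0/1	0/1	0/1	0/1
chr01	6900	ksnp17	A	T	.	PASS	.	GT	1/1	./.	1/1	1/1	1/1	1/1	1/1	1/1
chr01	7300	ksnp18	C	G	.	PASS	.	GT	0/1	./.	0/1	0/1	0/1	0/1	0/1	0/1
chr01	7700	ksnp19	A	T	.	PASS	.	GT	./.	0/1	0/1	0/1	0/1	0/0	0/0	0/0
chr01	8100	ksnp20	G	A	.	PASS	.	GT	./.	1/1	1/1	1/1	1/1	1/1	1/1	1/1
chr01	8500	ksnp21	T	C	.	PASS	.	GT	./.	0/1	0/1	0/1	0/1	0/1	0/1	0/0
chr01	8900	ksnp22	C	A	.	PASS	.	GT	./.	0/0	0/0	0/0	0/0	0/0	0/0	1/1
chr01	9300	ksnp23	T	C	.	PASS	.	GT	./.	0/0	0/0	0/0	0/0	0/0	0/1	0/0
chr01	9700	ksnp24	G	C	.	PASS	.	GT	./.	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr01	10100	ksnp25	A	C	.	PASS	.	GT	./.	0/0	0/0	0/0	0/0	0/0	1/1	0/0
chr01	10500	ksnp26	T	A	.	PASS	.	GT	./.	./.	0/0	0/0	0/0	0/0	0/0	0/0
chr01	10900	ksnp27	G	A	.	PASS	.	GT	./.	./.	0/0	0/0	0/0	0/0	0/0	0/0
chr01	11300	ksnp28	A	C	.	PASS	.	GT	./.	./.	0/0	0/0	0/0	0/0	0/0	0/0
chr01	11700	ksnp29	A	C	.	PASS	.	GT	./.	./.	0/0	0/0	0/0	0/0	0/1	0/0
chr01	12100	ksnp30	A	T	.	PASS	.	GT	./.	./.	0/0	0/0	0/0	0/0	0/0	0/0
chr01	12500	ksnp31	A	T	.	PASS	.	GT	./.	./.	1/1	1/1	1/1	1/1	0/1	1/1
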