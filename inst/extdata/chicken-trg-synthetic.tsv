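id	kind	subgroup	functionality	leader_end	fr1_start	fr1_end	cdr1_end	fr2_end	cdr2_end	fr3_end	rss_heptamer_pos	rss_spacer	contig	start	end	strand
Vg1.1	V	Vg1	ORF	45	0	69	105	156	186	312	NA	23	TRG_synthetic	90000	90364	+
Vg1.2	V	Vg1	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	88500	88864	+
Vg1.3	V	Vg1	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	87000	87364	+
Vg1.4	V	Vg1	pseudo	45	0	69	105	155	185	311	NA	23	TRG_synthetic	85500	85863	+
Vg1.5	V	Vg1	ORF	45	0	69	105	156	186	312	NA	23	TRG_synthetic	84000	84364	+
Vg1.6	V	Vg1	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	82500	82864	+
Vg2.1	V	Vg2	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	81000	81364	+
Vg2.2	V	Vg2	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	79500	79864	+
Vg2.3	V	Vg2	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	78000	78364	+
Vg2.4	V	Vg2	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	76500	76864	+
Vg2.5	V	Vg2	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	75000	75364	+
Vg2.6	V	Vg2	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	73500	73864	+
Vg2.7	V	Vg2	pseudo	45	0	69	105	156	186	312	NA	23	TRG_synthetic	72000	72364	+
Vg2.8	V	Vg2	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	70500	70864	+
Vg2.9	V	Vg2	pseudo	45	0	69	105	156	186	312	NA	23	TRG_synthetic	69000	69364	+
Vg2.10	V	Vg2	pseudo	45	0	69	105	156	186	312	NA	23	TRG_synthetic	67500	67864	+
Vg2.11	V	Vg2	pseudo	45	0	69	105	156	186	312	NA	23	TRG_synthetic	66000	66364	+
Vg2.12	V	Vg2	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	64500	64864	+
Vg2.13	V	Vg2	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	63000	63364	+
Vg2.14	V	Vg2	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	61500	61864	+
Vg2.15	V	Vg2	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	60000	60364	+
Vg2.16	V	Vg2	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	58500	58864	+
Vg2.17	V	Vg2	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	57000	57364	+
Vg2.18	V	Vg2	ORF	45	0	69	105	156	186	312	NA	23	TRG_synthetic	55500	55864	+
Vg2.19	V	Vg2	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	54000	54364	+
Vg3.1	V	Vg3	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	52500	52872	+
Vg3.2	V	Vg3	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	51000	51372	+
Vg3.3	V	Vg3	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	49500	49872	+
Vg3.4	V	Vg3	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	48000	48372	+
Vg3.5	V	Vg3	pseudo	45	0	69	105	156	186	312	NA	23	TRG_synthetic	46500	46872	+
Vg3.6	V	Vg3	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	45000	45372	+
Vg3.7	V	Vg3	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	43500	43872	+
Vg3.8	V	Vg3	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	42000	42372	+
Vg3.9	V	Vg3	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	40500	40872	+
Vg4.1	V	Vg4	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	39000	39362	+
Vg4.2	V	Vg4	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	37500	37862	+
Vg4.3	V	Vg4	functional	45	0	69	105	156	186	312	NA	23	TRG_synthetic	36000	36362	+
Vg4.4	V	Vg4	pseudo	45	0	69	105	156	186	312	NA	23	TRG_synthetic	34500	34862	+
Vg5.1	V	Vg5	pseudo	45	0	69	105	156	186	312	NA	23	TRG_synthetic	33000	33364	+
Vg5.2	V	Vg5	pseudo	45	0	69	105	156	186	312	NA	23	TRG_synthetic	31500	31864	+
Vg5.3	V	Vg5	pseudo	45	0	69	105	156	186	312	NA	23	TRG_synthetic	30000	30364	+
Vg6.1	V	Vg6	pseudo	45	0	69	105	156	186	312	NA	23	TRG_synthetic	28500	28864	+
Vg6.2	V	Vg6	pseudo	45	0	69	105	156	186	312	NA	23	TRG_synthetic	27000	27364	+
Vg6.3	V	Vg6	pseudo	45	0	69	105	156	186	312	NA	23	TRG_synthetic	25500	25864	+
Jg1	J	NA	functional	0	NA	NA	NA	NA	NA	NA	NA	12	TRG_synthetic	93000	93056	+
Jg2	J	NA	functional	0	NA	NA	NA	NA	NA	NA	NA	12	TRG_synthetic	93400	93456	+
Jg3	J	NA	functional	0	NA	NA	NA	NA	NA	NA	NA	12	TRG_synthetic	93800	93856	+
Cg	C	NA	functional	0	NA	NA	NA	NA	NA	NA	NA	NA	TRG_synthetic	95000	95150	+
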