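statistic	region	MW	MD
n_loci	whole	49	49
n_loci	coding	42	42
n_loci	intron	32	32
n_loci	utr5	2	2
n_loci	utr3	7	7
n_loci	noncoding	37	37
N	whole	18.6	19.7
N	coding	18.7	19.8
N	intron	18.7	19.8
N	utr5	18.0	20.0
N	utr3	19.0	20.0
N	noncoding	18.7	19.8
V	whole	411	218
V	coding	133	78
V	intron	218	103
V	utr5	8	0
V	utr3	16	11
V	noncoding	242	114
eta	whole	418	219
eta	coding	134	78
eta	intron	224	104
eta	utr5	8	0
eta	utr3	16	11
eta	noncoding	248	115
S	whole	123	67
S	coding	52	28
S	intron	60	35
S	utr5	1	0
S	utr3	5	1
S	noncoding	66	36
Pi	whole	288	151
Pi	coding	81	50
Pi	intron	158	68
Pi	utr5	7	0
Pi	utr3	11	10
Pi	noncoding	176	78
Syn	coding	82	45
Nonsyn	coding	50	32
H	whole	4.8	2.4
H	coding	3.1	2.0
H	intron	4.0	1.9
H	utr5	5.0	1.0
H	utr3	2.4	1.9
H	noncoding	4.0	1.9
Hd	whole	0.58	0.27
Hd	coding	0.38	0.20
Hd	intron	0.46	0.20
Hd	utr5	0.61	0.00
Hd	utr3	0.35	0.16
Hd	noncoding	0.48	0.20
pi_x1000	whole	5.39	2.70
pi_x1000	coding	3.29	1.69
pi_x1000	intron	7.63	3.29
pi_x1000	utr5	4.49	0.00
pi_x1000	utr3	5.54	3.51
pi_x1000	noncoding	7.66	3.45
theta_x1000	whole	5.26	2.64
theta_x1000	coding	3.09	1.77
theta_x1000	intron	7.61	3.11
theta_x1000	utr5	4.04	0.00
theta_x1000	utr3	5.11	3.46
theta_x1000	noncoding	7.47	3.24
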