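pattern	position	context	phoneme	precedence	label
A	any		æ	1	
B	any		b	2	
C	any	next=E,I,Y	s	3	C(before E/I/Y)
C	any		k	4	
D	any		d	5	
E	any		ɛ	6	
F	any		f	7	
G	any	next=E	ʤ	8	G(before E)
G	any		g	9	
H	any		h	10	
I	any		ɪ	11	
J	any		ʤ	12	
K	any		k	13	
L	any		l	14	
M	any		m	15	
N	any	next=C,K,Q	ŋ	16	N(before C/K/Q)
N	any		n	17	
O	any		ɒ	18	
P	any		p	19	
Q	any		k	20	
R	any		r	21	
S	any		s	22	
T	any		t	23	
U	any	prev=Q	w	24	U(after Q)
U	any		ʌ	25	
V	any		v	26	
W	any		w	27	
X	any		z	28	
Y	onset		j	29	Y(onset)
Y	any		aɪ	30	
Z	any		z	31	
SH	any		ʃ	32	
CH	any		ʧ	33	
TH	any		θ	34	
PH	any		f	35	
WH	onset		w	36	
GN	onset		n	37	
KN	onset		n	38	
PS	onset		s	39	
WR	onset		r	40	
CK	coda		k	41	
LL	any		l	42	
SS	any		s	43	
FF	any		f	44	
ZZ	any		z	45	
NG	coda		ŋ	46	
GE	coda		ʤ	47	
TCH	coda		ʧ	48	
DGE	coda		ʤ	49	
AI	any		eɪ	50	
AY	any		eɪ	51	
AU	any		ɔː	52	
AW	any		ɔː	53	
EA	any		iː	54	
EE	any		iː	55	
EI	any		eɪ	56	
EU	any		u	57	
EW	any		uː	58	
IE	any		iː	59	
OA	any		əʊ	60	
OE	any		əʊ	61	
OI	any		ɔɪ	62	
OY	any		ɔɪ	63	
OO	any		uː	64	
OU	any		aʊ	65	
OW	any		aʊ	66	
UE	any		uː	67	
UI	any		uː	68	
AR	any		ɑː	69	
ER	any		ɜː	70	
IR	any		ɜː	71	
OR	any		ɔː	72	
UR	any		ɜː	73	
A.E	any		eɪ	74	
E.E	any		iː	75	
I.E	any		aɪ	76	
O.E	any		əʊ	77	
U.E	any		uː	78	
A.UE	any		æ	79	
I.UE	any		iː	80	
U.UE	any		ʌ	81	
AI.E	any		eɪ	82	
AU.E	any		əʊ	83	
EU.E	any		uː	84	
IE.E	any		iː	85	
OA.E	any		ɔː	86	
OU.E	any		uː	87	
UI.E	any		aɪ	88	
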