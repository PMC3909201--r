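# Miyazawa-Jernigan effective inter-residue contact energies e_ij (1996 revision,
# Table V), in RT units.  Upper triangle, residues in the original table order.
# Used as raw magnitudes |e_ij| for native-contact weights; downstream code
# renormalises the weights on each contact list to unit mean, so only relative
# magnitudes matter.
res_i	res_j	e_ij
C	C	-5.44
C	M	-4.99
C	F	-5.80
C	I	-5.50
C	L	-5.83
C	V	-4.96
C	W	-4.95
C	Y	-4.16
C	A	-3.57
C	G	-3.16
C	T	-3.11
C	S	-2.86
C	N	-2.59
C	Q	-2.85
C	D	-2.41
C	E	-2.27
C	H	-3.60
C	R	-2.57
C	K	-1.95
C	P	-3.07
M	M	-5.46
M	F	-6.56
M	I	-6.02
M	L	-6.41
M	V	-5.32
M	W	-5.55
M	Y	-4.91
M	A	-3.94
M	G	-3.39
M	T	-3.51
M	S	-3.03
M	N	-2.95
M	Q	-3.30
M	D	-2.57
M	E	-2.89
M	H	-3.98
M	R	-3.12
M	K	-2.48
M	P	-3.45
F	F	-7.26
F	I	-6.84
F	L	-7.28
F	V	-6.29
F	W	-6.16
F	Y	-5.66
F	A	-4.81
F	G	-4.13
F	T	-4.28
F	S	-4.02
F	N	-3.75
F	Q	-4.10
F	D	-3.48
F	E	-3.56
F	H	-4.77
F	R	-3.98
F	K	-3.36
F	P	-4.25
I	I	-6.54
I	L	-7.04
I	V	-6.05
I	W	-5.78
I	Y	-5.25
I	A	-4.58
I	G	-3.78
I	T	-4.03
I	S	-3.52
I	N	-3.24
I	Q	-3.67
I	D	-3.17
I	E	-3.27
I	H	-4.14
I	R	-3.63
I	K	-3.01
I	P	-3.76
L	L	-7.37
L	V	-6.48
L	W	-6.14
L	Y	-5.67
L	A	-4.91
L	G	-4.16
L	T	-4.34
L	S	-3.92
L	N	-3.74
L	Q	-4.04
L	D	-3.40
L	E	-3.59
L	H	-4.54
L	R	-4.03
L	K	-3.37
L	P	-4.20
V	V	-5.52
V	W	-5.18
V	Y	-4.62
V	A	-4.04
V	G	-3.38
V	T	-3.46
V	S	-3.05
V	N	-2.83
V	Q	-3.07
V	D	-2.48
V	E	-2.67
V	H	-3.58
V	R	-3.07
V	K	-2.49
V	P	-3.32
W	W	-5.06
W	Y	-4.66
W	A	-3.82
W	G	-3.42
W	T	-3.22
W	S	-2.99
W	N	-3.07
W	Q	-3.11
W	D	-2.84
W	E	-2.99
W	H	-3.98
W	R	-3.41
W	K	-2.69
W	P	-3.73
Y	Y	-4.17
Y	A	-3.36
Y	G	-3.01
Y	T	-3.01
Y	S	-2.78
Y	N	-2.76
Y	Q	-2.97
Y	D	-2.76
Y	E	-2.79
Y	H	-3.52
Y	R	-3.16
Y	K	-2.60
Y	P	-3.19
A	A	-2.72
A	G	-2.31
A	T	-2.32
A	S	-2.01
A	N	-1.84
A	Q	-1.89
A	D	-1.70
A	E	-1.51
A	H	-2.41
A	R	-1.83
A	K	-1.31
A	P	-2.03
G	G	-2.24
G	T	-2.08
G	S	-1.82
G	N	-1.74
G	Q	-1.66
G	D	-1.59
G	E	-1.22
G	H	-2.15
G	R	-1.72
G	K	-1.15
G	P	-1.87
T	T	-2.12
T	S	-1.96
T	N	-1.88
T	Q	-1.90
T	D	-1.80
T	E	-1.74
T	H	-2.42
T	R	-1.90
T	K	-1.31
T	P	-1.90
S	S	-1.67
S	N	-1.58
S	Q	-1.49
S	D	-1.63
S	E	-1.48
S	H	-2.11
S	R	-1.62
S	K	-1.05
S	P	-1.57
N	N	-1.68
N	Q	-1.71
N	D	-1.68
N	E	-1.51
N	H	-2.08
N	R	-1.64
N	K	-1.21
N	P	-1.53
Q	Q	-1.54
Q	D	-1.46
Q	E	-1.42
Q	H	-1.98
Q	R	-1.80
Q	K	-1.29
Q	P	-1.73
D	D	-1.21
D	E	-1.02
D	H	-2.32
D	R	-2.29
D	K	-1.68
D	P	-1.33
E	E	-0.91
E	H	-2.15
E	R	-2.27
E	K	-1.80
E	P	-1.26
H	H	-3.05
H	R	-2.16
H	K	-1.35
H	P	-2.25
R	R	-1.55
R	K	-0.59
R	P	-1.70
K	K	-0.12
K	P	-0.97
P	P	-1.75
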