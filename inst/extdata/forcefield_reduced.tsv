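resname	atomname	charge	sigma_nm	epsilon_kJmol
GLY	N	-0.5	0.3	0.4
GLY	H	0.5	0.3	0
GLY	CA	0	0.35	0.4
GLY	C	0.5	0.35	0.4
GLY	O	-0.5	0.3	0.4
ALA	N	-0.5	0.3	0.4
ALA	H	0.5	0.3	0
ALA	CA	0	0.35	0.4
ALA	C	0.5	0.35	0.4
ALA	O	-0.5	0.3	0.4
ALA	CB	0	0.35	0.4
SER	N	-0.5	0.3	0.4
SER	H	0.5	0.3	0
SER	CA	0	0.35	0.4
SER	C	0.5	0.35	0.4
SER	O	-0.5	0.3	0.4
SER	CB	0	0.35	0.4
SER	OG	-0.5	0.3	0.4
SER	HG	0.5	0.3	0
THR	N	-0.5	0.3	0.4
THR	H	0.5	0.3	0
THR	CA	0	0.35	0.4
THR	C	0.5	0.35	0.4
THR	O	-0.5	0.3	0.4
THR	CB	0	0.35	0.4
THR	OG1	-0.5	0.3	0.4
THR	HG1	0.5	0.3	0
THR	CG2	0	0.35	0.4
CYS	N	-0.5	0.3	0.4
CYS	H	0.5	0.3	0
CYS	CA	0	0.35	0.4
CYS	C	0.5	0.35	0.4
CYS	O	-0.5	0.3	0.4
CYS	CB	0	0.35	0.4
CYS	SG	0	0.35	0.4
VAL	N	-0.5	0.3	0.4
VAL	H	0.5	0.3	0
VAL	CA	0	0.35	0.4
VAL	C	0.5	0.35	0.4
VAL	O	-0.5	0.3	0.4
VAL	CB	0	0.35	0.4
VAL	CG1	0	0.35	0.4
VAL	CG2	0	0.35	0.4
LEU	N	-0.5	0.3	0.4
LEU	H	0.5	0.3	0
LEU	CA	0	0.35	0.4
LEU	C	0.5	0.35	0.4
LEU	O	-0.5	0.3	0.4
LEU	CB	0	0.35	0.4
LEU	CG	0	0.35	0.4
LEU	CD1	0	0.35	0.4
LEU	CD2	0	0.35	0.4
ILE	N	-0.5	0.3	0.4
ILE	H	0.5	0.3	0
ILE	CA	0	0.35	0.4
ILE	C	0.5	0.35	0.4
ILE	O	-0.5	0.3	0.4
ILE	CB	0	0.35	0.4
ILE	CG1	0	0.35	0.4
ILE	CG2	0	0.35	0.4
ILE	CD1	0	0.35	0.4
MET	N	-0.5	0.3	0.4
MET	H	0.5	0.3	0
MET	CA	0	0.35	0.4
MET	C	0.5	0.35	0.4
MET	O	-0.5	0.3	0.4
MET	CB	0	0.35	0.4
MET	CG	0	0.35	0.4
MET	SD	0	0.35	0.4
MET	CE	0	0.35	0.4
PRO	N	0	0.3	0.4
PRO	CA	0	0.35	0.4
PRO	C	0.5	0.35	0.4
PRO	O	-0.5	0.3	0.4
PRO	CB	0	0.35	0.4
PRO	CG	0	0.35	0.4
PRO	CD	0	0.35	0.4
PHE	N	-0.5	0.3	0.4
PHE	H	0.5	0.3	0
PHE	CA	0	0.35	0.4
PHE	C	0.5	0.35	0.4
PHE	O	-0.5	0.3	0.4
PHE	CB	0	0.35	0.4
PHE	CG	0	0.35	0.4
PHE	CD1	0	0.35	0.4
PHE	CD2	0	0.35	0.4
PHE	CE1	0	0.35	0.4
PHE	CE2	0	0.35	0.4
PHE	CZ	0	0.35	0.4
TYR	N	-0.5	0.3	0.4
TYR	H	0.5	0.3	0
TYR	CA	0	0.35	0.4
TYR	C	0.5	0.35	0.4
TYR	O	-0.5	0.3	0.4
TYR	CB	0	0.35	0.4
TYR	CG	0	0.35	0.4
TYR	CD1	0	0.35	0.4
TYR	CD2	0	0.35	0.4
TYR	CE1	0	0.35	0.4
TYR	CE2	0	0.35	0.4
TYR	CZ	0	0.35	0.4
TYR	OH	-0.5	0.3	0.4
TYR	HH	0.5	0.3	0
TRP	N	-0.5	0.3	0.4
TRP	H	0.5	0.3	0
TRP	CA	0	0.35	0.4
TRP	C	0.5	0.35	0.4
TRP	O	-0.5	0.3	0.4
TRP	CB	0	0.35	0.4
TRP	CG	0	0.35	0.4
TRP	CD1	0	0.35	0.4
TRP	CD2	0	0.35	0.4
TRP	NE1	-0.5	0.3	0.4
TRP	HE1	0.5	0.3	0
TRP	CE2	0	0.35	0.4
TRP	CE3	0	0.35	0.4
TRP	CZ2	0	0.35	0.4
TRP	CZ3	0	0.35	0.4
TRP	CH2	0	0.35	0.4
HIS	N	-0.5	0.3	0.4
HIS	H	0.5	0.3	0
HIS	CA	0	0.35	0.4
HIS	C	0.5	0.35	0.4
HIS	O	-0.5	0.3	0.4
HIS	CB	0	0.35	0.4
HIS	CG	0	0.35	0.4
HIS	ND1	-0.5	0.3	0.4
HIS	CD2	0	0.35	0.4
HIS	CE1	0.5	0.35	0.4
HIS	NE2	-0.5	0.3	0.4
HIS	HE2	0.5	0.3	0
LYS	N	-0.5	0.3	0.4
LYS	H	0.5	0.3	0
LYS	CA	0	0.35	0.4
LYS	C	0.5	0.35	0.4
LYS	O	-0.5	0.3	0.4
LYS	CB	0	0.35	0.4
LYS	NZ	1	0.3	0.4
LYS	HZ1	0	0.3	0
LYS	HZ2	0	0.3	0
LYS	HZ3	0	0.3	0
ARG	N	-0.5	0.3	0.4
ARG	H	0.5	0.3	0
ARG	CA	0	0.35	0.4
ARG	C	0.5	0.35	0.4
ARG	O	-0.5	0.3	0.4
ARG	CB	0	0.35	0.4
ARG	CZ	0	0.35	0.4
ARG	NH1	0.5	0.3	0.4
ARG	HH11	0	0.3	0
ARG	HH12	0	0.3	0
ARG	NH2	0.5	0.3	0.4
ARG	HH21	0	0.3	0
ARG	HH22	0	0.3	0
ASP	N	-0.5	0.3	0.4
ASP	H	0.5	0.3	0
ASP	CA	0	0.35	0.4
ASP	C	0.5	0.35	0.4
ASP	O	-0.5	0.3	0.4
ASP	CB	0	0.35	0.4
ASP	CG	0	0.35	0.4
ASP	OD1	-0.5	0.3	0.4
ASP	OD2	-0.5	0.3	0.4
GLU	N	-0.5	0.3	0.4
GLU	H	0.5	0.3	0
GLU	CA	0	0.35	0.4
GLU	C	0.5	0.35	0.4
GLU	O	-0.5	0.3	0.4
GLU	CB	0	0.35	0.4
GLU	CG	0	0.35	0.4
GLU	CD	0	0.35	0.4
GLU	OE1	-0.5	0.3	0.4
GLU	OE2	-0.5	0.3	0.4
ASN	N	-0.5	0.3	0.4
ASN	H	0.5	0.3	0
ASN	CA	0	0.35	0.4
ASN	C	0.5	0.35	0.4
ASN	O	-0.5	0.3	0.4
ASN	CB	0	0.35	0.4
ASN	CG	0	0.35	0.4
ASN	OD1	-0.5	0.3	0.4
ASN	ND2	-0.5	0.3	0.4
ASN	HD21	0.5	0.3	0
ASN	HD22	0.5	0.3	0
GLN	N	-0.5	0.3	0.4
GLN	H	0.5	0.3	0
GLN	CA	0	0.35	0.4
GLN	C	0.5	0.35	0.4
GLN	O	-0.5	0.3	0.4
GLN	CB	0	0.35	0.4
GLN	CG	0	0.35	0.4
GLN	CD	0	0.35	0.4
GLN	OE1	-0.5	0.3	0.4
GLN	NE2	-0.5	0.3	0.4
GLN	HE21	0.5	0.3	0
GLN	HE22	0.5	0.3	0
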