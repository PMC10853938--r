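# default retained element pairs for the Born pair-energy features (36 of
# the 45 possible pairs of H C N O F S Cl Br I; the 9 halogen-halogen and
# S-Br/S-I combinations rarest in organic solutes are dropped).  Editable:
# any subset of the 45 pairs, one pair per line, defines a valid schema.
el1	el2
H	H
H	C
H	N
H	O
H	F
H	S
H	Cl
H	Br
H	I
C	C
C	N
C	O
C	F
C	S
C	Cl
C	Br
C	I
N	N
N	O
N	F
N	S
N	Cl
N	Br
N	I
O	O
O	F
O	S
O	Cl
O	Br
O	I
F	F
F	S
F	Cl
S	S
S	Cl
Cl	Cl
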