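codon	amino_acid	status
TTT	F	unpreferred
TTC	F	preferred
TTA	L	unpreferred
TTG	L	unpreferred
TCT	S	unpreferred
TCC	S	preferred
TCA	S	unpreferred
TCG	S	unpreferred
TAT	Y	unpreferred
TAC	Y	preferred
TAA	*	not_applicable
TAG	*	not_applicable
TGT	C	unpreferred
TGC	C	preferred
TGA	*	not_applicable
TGG	W	not_applicable
CTT	L	unpreferred
CTC	L	unpreferred
CTA	L	unpreferred
CTG	L	preferred
CCT	P	unpreferred
CCC	P	preferred
CCA	P	unpreferred
CCG	P	unpreferred
CAT	H	unpreferred
CAC	H	preferred
CAA	Q	unpreferred
CAG	Q	preferred
CGT	R	unpreferred
CGC	R	preferred
CGA	R	unpreferred
CGG	R	unpreferred
ATT	I	unpreferred
ATC	I	preferred
ATA	I	unpreferred
ATG	M	not_applicable
ACT	T	unpreferred
ACC	T	preferred
ACA	T	unpreferred
ACG	T	unpreferred
AAT	N	unpreferred
AAC	N	preferred
AAA	K	unpreferred
AAG	K	preferred
AGT	S	unpreferred
AGC	S	unpreferred
AGA	R	unpreferred
AGG	R	unpreferred
GTT	V	unpreferred
GTC	V	unpreferred
GTA	V	unpreferred
GTG	V	preferred
GCT	A	unpreferred
GCC	A	preferred
GCA	A	unpreferred
GCG	A	unpreferred
GAT	D	unpreferred
GAC	D	preferred
GAA	E	unpreferred
GAG	E	preferred
GGT	G	unpreferred
GGC	G	preferred
GGA	G	unpreferred
GGG	G	unpreferred
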