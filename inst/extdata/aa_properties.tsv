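code	name	hydropathy_class	polarity_class	kd_value
A	Alanine	hydrophobic	nonpolar	1.8
R	Arginine	hydrophilic	positive	-4.5
N	Asparagine	hydrophilic	polar_uncharged	-3.5
D	Aspartate	hydrophilic	negative	-3.5
C	Cysteine	hydrophobic	nonpolar	2.5
Q	Glutamine	hydrophilic	polar_uncharged	-3.5
E	Glutamate	hydrophilic	negative	-3.5
G	Glycine	hydrophilic	nonpolar	-0.4
H	Histidine	hydrophilic	positive	-3.2
I	Isoleucine	hydrophobic	nonpolar	4.5
L	Leucine	hydrophobic	nonpolar	3.8
K	Lysine	hydrophilic	positive	-3.9
M	Methionine	hydrophobic	nonpolar	1.9
F	Phenylalanine	hydrophobic	nonpolar	2.8
P	Proline	hydrophilic	nonpolar	-1.6
S	Serine	hydrophilic	polar_uncharged	-0.8
T	Threonine	hydrophilic	polar_uncharged	-0.7
W	Tryptophan	hydrophilic	nonpolar	-0.9
Y	Tyrosine	hydrophilic	polar_uncharged	-1.3
V	Valine	hydrophobic	nonpolar	4.2
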