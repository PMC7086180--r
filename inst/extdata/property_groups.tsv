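# Amino-acid biochemical property partition used for radical-change calls:
# charge-first grouping (acidic, basic, polar/other, hydrophobic).
residue	group
D	acidic
E	acidic
K	basic
R	basic
H	basic
S	polar
T	polar
N	polar
Q	polar
C	polar
G	polar
P	polar
Y	polar
A	hydrophobic
V	hydrophobic
L	hydrophobic
I	hydrophobic
M	hydrophobic
F	hydrophobic
W	hydrophobic
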