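residue,name,ges_score,increment,midi_pitch
F,Phenylalanine,-3.7,NA,50
M,Methionine,-3.4,0.3,51
I,Isoleucine,-3.1,0.3,52
L,Leucine,-2.8,0.3,53
V,Valine,-2.6,0.2,54
C,Cysteine,-2,0.6,55
W,Tryptophan,-1.9,0.1,56
A,Alanine,-1.6,0.3,57
T,Threonine,-1.2,0.4,58
G,Glycine,-1,0.2,59
S,Serine,-0.6,0.4,60
P,Proline,0.2,0.8,61
Y,Tyrosine,0.7,0.5,62
H,Histidine,3,2.3,65
Q,Glutamine,4.1,1.1,66
N,Asparagine,4.8,0.7,67
E,Glutamate,8.2,3.4,71
K,Lysine,8.8,0.6,72
D,Aspartate,9.2,0.4,73
R,Arginine,12.3,3.1,77
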