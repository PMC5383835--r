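# classification: hydropathy-synthetic
AAA	hydrophilic
AAC	hydrophilic
AAG	hydrophilic
AAU	hydrophilic
ACA	moderately-hydrophobic
ACC	moderately-hydrophobic
ACG	moderately-hydrophobic
ACU	moderately-hydrophobic
AGA	hydrophilic
AGC	moderately-hydrophobic
AGG	hydrophilic
AGU	moderately-hydrophobic
AUA	very-hydrophobic
AUC	very-hydrophobic
AUG	very-hydrophobic
AUU	very-hydrophobic
CAA	hydrophilic
CAC	hydrophilic
CAG	hydrophilic
CAU	hydrophilic
CCA	moderately-hydrophobic
CCC	moderately-hydrophobic
CCG	moderately-hydrophobic
CCU	moderately-hydrophobic
CGA	hydrophilic
CGC	hydrophilic
CGG	hydrophilic
CGU	hydrophilic
CUA	very-hydrophobic
CUC	very-hydrophobic
CUG	very-hydrophobic
CUU	very-hydrophobic
GAA	hydrophilic
GAC	hydrophilic
GAG	hydrophilic
GAU	hydrophilic
GCA	hydrophobic
GCC	hydrophobic
GCG	hydrophobic
GCU	hydrophobic
GGA	moderately-hydrophobic
GGC	moderately-hydrophobic
GGG	moderately-hydrophobic
GGU	moderately-hydrophobic
GUA	very-hydrophobic
GUC	very-hydrophobic
GUG	very-hydrophobic
GUU	very-hydrophobic
UAC	moderately-hydrophobic
UAU	moderately-hydrophobic
UCA	moderately-hydrophobic
UCC	moderately-hydrophobic
UCG	moderately-hydrophobic
UCU	moderately-hydrophobic
UGA	moderately-hydrophobic
UGC	hydrophobic
UGG	moderately-hydrophobic
UGU	hydrophobic
UUA	very-hydrophobic
UUC	hydrophobic
UUG	very-hydrophobic
UUU	hydrophobic
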