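# classification: polarity-synthetic
AAA	polar
AAC	polar
AAG	polar
AAU	polar
ACA	polar
ACC	polar
ACG	polar
ACU	polar
AGA	polar
AGC	polar
AGG	polar
AGU	polar
AUA	non-polar
AUC	non-polar
AUG	non-polar
AUU	non-polar
CAA	polar
CAC	polar
CAG	polar
CAU	polar
CCA	non-polar
CCC	non-polar
CCG	non-polar
CCU	non-polar
CGA	polar
CGC	polar
CGG	polar
CGU	polar
CUA	non-polar
CUC	non-polar
CUG	non-polar
CUU	non-polar
GAA	polar
GAC	polar
GAG	polar
GAU	polar
GCA	non-polar
GCC	non-polar
GCG	non-polar
GCU	non-polar
GGA	polar
GGC	polar
GGG	polar
GGU	polar
GUA	non-polar
GUC	non-polar
GUG	non-polar
GUU	non-polar
UAA	polar
UAC	polar
UAG	polar
UAU	polar
UCA	polar
UCC	polar
UCG	polar
UCU	polar
UGA	non-polar
UGC	non-polar
UGG	non-polar
UGU	non-polar
UUA	non-polar
UUC	non-polar
UUG	non-polar
UUU	non-polar
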