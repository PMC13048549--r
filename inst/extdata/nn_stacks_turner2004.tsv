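# Nearest-neighbour helix stack free energies, Turner 2004 rules
# dG degrees37 in kcal/mol for stacked pair steps 5'XY3'/3'(reverse of WZ)5',
# written as XY/WZ with both strands read 5'->3'. Watson-Crick and GU
# wobble steps. Transcribed from the ViennaRNA 2.7.2 default (Turner
# 2004) parameter set via fixed-structure evaluation of two-pair
# helices (duplex initiation 4.10, terminal AU/GU penalty 0.50
# removed); the ten Watson-Crick values agree with Xia et al. 1998.
step	dG37_kcal_mol
AA/UU	-0.90
AC/GU	-2.20
AG/CU	-2.10
AG/UU	-0.60
AU/AU	-1.10
AU/GU	-1.40
CA/UG	-2.10
CC/GG	-3.30
CG/CG	-2.40
CG/UG	-1.40
CU/AG	-2.10
CU/GG	-2.10
GA/UC	-2.40
GA/UU	-1.30
GC/GC	-3.40
GC/GU	-2.50
GG/CC	-3.30
GG/CU	-2.10
GG/UC	-1.50
GG/UU	-0.50
GU/AC	-2.20
GU/AU	-1.40
GU/GC	-2.50
GU/GU	1.30
UA/UA	-1.30
UA/UG	-1.00
UC/GA	-2.40
UC/GG	-1.50
UG/CA	-2.10
UG/CG	-1.40
UG/UA	-1.00
UG/UG	0.30
UU/AA	-0.90
UU/AG	-0.60
UU/GA	-1.30
UU/GG	-0.50
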