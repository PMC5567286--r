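# RNA/RNA nearest-neighbor stacking free energies, kcal/mol at 37 C
# top5p: duplex strand read 5p->3p; bottom3p: paired strand read 3p->5p
# (top5p[1] pairs bottom3p[1]); Watson-Crick and G:U pairs only.
# Values transcribed from the Turner 2004 parameter set; INIT is the
# duplex initiation penalty. Edit and pass via duplex_energy(energy_table=).
top5p	bottom3p	dG37
INIT	.	4.09
AA	UU	-0.9
AC	UG	-2.2
AG	UC	-2.1
AG	UU	-0.6
AU	UA	-1.1
AU	UG	-1.4
CA	GU	-2.1
CC	GG	-3.3
CG	GC	-2.4
CG	GU	-1.4
CU	GA	-2.1
CU	GG	-2.1
GA	CU	-2.4
GA	UU	-1.3
GC	CG	-3.4
GC	UG	-2.5
GG	CC	-3.3
GG	CU	-1.5
GG	UC	-2.1
GG	UU	-0.5
GU	CA	-2.2
GU	CG	-2.5
GU	UA	-1.4
GU	UG	1.3
UA	AU	-1.3
UA	GU	-1
UC	AG	-2.4
UC	GG	-1.5
UG	AC	-2.1
UG	AU	-1
UG	GC	-1.4
UG	GU	0.3
UU	AA	-0.9
UU	AG	-1.3
UU	GA	-0.6
UU	GG	-0.5
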