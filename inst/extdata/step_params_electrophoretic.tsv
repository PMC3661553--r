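# Electrophoretically estimated dinucleotide step parameters (wedge model).
# twist, wedge, direction in degrees; rise in Angstrom; stacking in kcal/mol.
# twist/wedge/direction: gel-mobility-derived wedge angles of Bolshoy et al.
#   (PNAS 1991) as distributed in DiProDB. direction is the in-plane azimuth of
#   the wedge rotation axis measured in the mid-step frame, so that the
#   reverse-complement step has direction of opposite sign
#   (roll = wedge*cos(direction), tilt = wedge*sin(direction)).
# rise: canonical B-DNA helical rise, 3.4 A for every step.
# stacking: dinucleotide base-stacking energies of Ornstein et al. (1978) as
#   distributed in DiProDB; symmetric under reverse complement.
dinucleotide	twist	wedge	direction	rise	stacking
AA	35.62	7.2	-154	3.4	-5.37
AC	34.40	1.1	143	3.4	-10.51
AG	27.70	8.4	2	3.4	-6.78
AT	31.50	2.6	0	3.4	-6.57
CA	34.50	3.5	-64	3.4	-6.57
CC	33.67	2.1	-57	3.4	-8.26
CG	29.80	6.7	0	3.4	-9.69
CT	27.70	8.4	-2	3.4	-6.78
GA	36.90	5.3	120	3.4	-9.81
GC	40.00	5.0	180	3.4	-14.59
GG	33.67	2.1	57	3.4	-8.26
GT	34.40	1.1	-143	3.4	-10.51
TA	36.00	0.9	0	3.4	-3.82
TC	36.90	5.3	-120	3.4	-9.81
TG	34.50	3.5	64	3.4	-6.57
TT	35.62	7.2	154	3.4	-5.37
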