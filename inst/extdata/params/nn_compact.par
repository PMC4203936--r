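# Compact nearest-neighbor free-energy table (kcal/mol, 37 C scale).
# Watson-Crick/wobble helix stacks plus loop initiation penalties in the
# style of the standard nearest-neighbor rules; no dangling ends, no
# coaxial stacking, no tetraloop bonuses.  Format: one keyword per line.
# stack <pair5'> <pair3'> <dG>: pair XY means X paired to Y; the two
# pairs read 5'->3' on the top strand.
name nn-compact-1
rt 0.616
min_hairpin 3
max_interior 30
terminal_au 0.5
ml_close 3.4
ml_branch 0.4
ml_unpaired 0.0
loop_extrapolation 1.75
interior_asym 0.6
interior_asym_max 3.0
stack AU AU -0.93
stack AU UA -1.10
stack AU CG -2.24
stack AU GC -2.08
stack AU GU -0.50
stack AU UG -0.70
stack UA AU -1.33
stack UA UA -0.93
stack UA CG -2.35
stack UA GC -2.11
stack UA GU -0.60
stack UA UG -0.50
stack CG AU -2.11
stack CG UA -2.08
stack CG CG -3.26
stack CG GC -2.36
stack CG GU -1.50
stack CG UG -1.40
stack GC AU -2.35
stack GC UA -2.24
stack GC CG -3.42
stack GC GC -3.26
stack GC GU -1.30
stack GC UG -2.10
stack GU AU -0.50
stack GU UA -0.70
stack GU CG -2.10
stack GU GC -1.40
stack GU GU -0.50
stack GU UG 0.47
stack UG AU -0.60
stack UG UA -0.50
stack UG CG -1.30
stack UG GC -1.50
stack UG GU -0.60
stack UG UG -0.50
hairpin 3 5.4
hairpin 4 5.6
hairpin 5 5.7
hairpin 6 5.4
hairpin 7 6.0
hairpin 8 5.5
hairpin 9 6.4
bulge 1 3.8
bulge 2 2.8
bulge 3 3.2
bulge 4 3.6
bulge 5 4.0
bulge 6 4.4
interior 2 0.8
interior 3 1.3
interior 4 1.7
interior 5 1.8
interior 6 2.0
interior 7 2.2
interior 8 2.3
interior 9 2.4
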