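# Default van der Waals radius table (Bondi), Angstrom.
# Edit or extend (e.g., add SE) and pass to parse_structure()/
# assign_vdw_radii() via read_radius_table().
C  1.70
N  1.55
O  1.52
S  1.80
P  1.80
F  1.47
CL 1.75
BR 1.85
I  1.98
ZN 1.39
CU 1.40
H  1.20
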