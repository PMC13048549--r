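# Twin-drive strand-selection constants: ln(5p/3p) = k*ddG(5p-3p) + N(5p) - N(3p)
# after the twin-drive model of small-RNA asymmetry (its source publication
# fitted the constants on murine miRNAs; they were not optimized for
# C. elegans). These packaged defaults are NOT a transcription of that
# publication's fitted values: they are package defaults that preserve the
# published sign structure on this package's unwinding-cost energy scale
# (ddG > 0 = stable end, so k < 0: a harder-to-unwind 5p end disfavours the
# 5p strand) and the 5'-nucleotide preference ordering U > A > G > C.
# Replace with fitted constants via twinDriveParams(path=...) to reproduce
# a specific publication's calibration.
# k is per kcal/mol; N values are dimensionless drives for the 5'-terminal
# nucleotide of each strand.
constant	value
k	-0.5
N_U	1.2
N_A	0.8
N_G	0.4
N_C	0.0
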