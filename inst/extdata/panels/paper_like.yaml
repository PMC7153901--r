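# Design of the paper-like synthetic expression study.
# Fixed design values: 137 bound genes, 94 signaling-dependent genes of which
# 2 are planted primaries (bound) and 3 planted secondaries (unbound,
# target-dependent, decay lagged by the 2 h regulator-protein half-life),
# 5 replicates per condition for the ON/OFF contrast, 4 replicates per
# degradation time point, time points 0/0.5/1/2/4/48 h (counts generated at
# the sequencing points 0/2/4/48; 0.5 and 1 h are qPCR-only).
# Noise settings (dispersion, library size, mean-abundance range) are chosen
# for planted-truth recovery with a plain two-sample test, not for realism.
name: paper_like
n_genes: 2000
n_bound: 137
n_dependent: 94
n_primaries: 2
n_secondaries: 3
reps: 5
tc_reps: 4
timepoints: [0, 0.5, 1, 2, 4, 48]
rnaseq_timepoints: [0, 2, 4, 48]
dispersion: 0.01
library_size: 2000000
floor_fraction: 0.05
primary_half_life: 1.0
secondary_half_life: 1.0
secondary_lag: 2.0
other_half_life: 6.0
other_lag: 6.0
log2fc_levels: [2.5, 3, 3.5, 4]
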