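# Assay designs used throughout the tests: the 16-point MST dilution
# series (0.005-500 uM) and the 11-point traditional-assay series for
# papaverine (0.25-250 uM).
mst_design <- 10^seq(log10(500), log10(0.005), length.out = 16)
papaverine_design <- 250 / 2^(0:10)

# published Sips parameters used as simulation truths
chloroquine_sips <- function() sips_parameters(kd = 76, bmax = 380, n = 0.605)
papaverine_sips <- function() sips_parameters(kd = 66, bmax = 66, n = 0.715)
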