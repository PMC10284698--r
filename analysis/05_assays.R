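#!/usr/bin/env Rscript
# Bioadhesion index: aggregate bacterial-adhesion and protein-adsorption
# assay results, each normalized to the cholesterol SCL, into one index per
# surface, with the bare-substrate reference value.

suppressPackageStartupMessages(library(sterolentropy))
dir.create("results", showWarnings = FALSE)

tab <- gen_assay_table(seed = 11)
write_pipeline_csv(tab, "results/assay_table.csv",
                   meta = list(generator = "gen_assay_table", seed = 11))

norm <- normalize_assays(tab)
idx <- bioadhesion_index(norm)
print(idx)

## example of the count-scaling step feeding the bacterial assays:
cat(sprintf("\n(count scaling: 10 cells in 1e3 um^2 = %g cells/mm^2)\n",
            scale_cell_counts(10, 1e3)))

write_pipeline_csv(idx$index, "results/bioadhesion_index.csv",
                   meta = list(aggregate = idx$aggregate,
                               reference_value = idx$reference_value))
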