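#!/usr/bin/env Rscript
# Regenerates inst/extdata/reference_synthetic/ from the package's own
# blueprint generator. Deterministic; run from the repository root after
# changing the generator or the blueprint defaults.
suppressPackageStartupMessages(library(clcscan))

dir <- "inst/extdata/reference_synthetic"
dir.create(dir, recursive = TRUE, showWarnings = FALSE)

# the scaffold: fully featured, canonical background, no divergence
bp <- clc_blueprint(filter_residue2 = "P", divergence = 0,
                    background_seed = 42L, seed = 7L)
scaffold <- generate_clc_protein(bp, id = "CLC_SCAFFOLD_SYNTH")
truth <- scaffold$truth

feat <- function(f) truth[truth$feature == f, , drop = FALSE]
meta <- list(
  synthetic = TRUE,
  note = paste("Synthetic CLC scaffold generated by clc_blueprint();",
               "stand-in for a real anchor reference such as EcCLC."),
  gating = feat("gating_glutamate")$start,
  proton = feat("proton_glutamate")$start,
  filter_start = feat("GxGxPE")$start,
  filter_len = 6L)

write_fasta(scaffold$record, file.path(dir, "reference.fasta"))
jsonlite::write_json(meta, file.path(dir, "anchors.json"),
                     auto_unbox = TRUE, pretty = TRUE)

cbs <- synthetic_cbs_segments()
write_fasta(clc_seqs(names(cbs), unname(cbs),
                     description = rep("synthetic CBS reference segment", 2)),
            file.path(dir, "cbs.fasta"))

# homolog panel: same background, varied features/divergence
hom_specs <- list(
  list(id = "HOM_A_SYNTH", r2 = "P",  div = 0.10, seed = 101L),
  list(id = "HOM_B_SYNTH", r2 = "P",  div = 0.20, seed = 102L),
  list(id = "HOM_C_SYNTH", r2 = "S",  div = 0.15, seed = 103L),
  list(id = "HOM_D_SYNTH", r2 = "S",  div = 0.30, seed = 104L))
homs <- lapply(hom_specs, function(h) {
  b <- clc_blueprint(filter_residue2 = h$r2, divergence = h$div,
                     background_seed = 42L, seed = h$seed)
  generate_clc_protein(b, id = h$id)$record
})
all <- do.call(rbind, lapply(homs, as.data.frame))
write_fasta(clc_seqs(all$id, all$sequence,
                     description = rep("synthetic homolog", nrow(all))),
            file.path(dir, "homologs.fasta"))
message("bundle written to ", dir)
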