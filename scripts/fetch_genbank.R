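#!/usr/bin/env Rscript
# Optional helper (needs network; OUTSIDE the tested core): fetches the
# seven deposited CDS records, translates them and writes the protein
# FASTA that check_table1() consumes.
#
#   Rscript scripts/fetch_genbank.R saclc_proteins.fasta

suppressPackageStartupMessages(library(clcscan))

accessions <- c(SaCLCa1 = "KX013489.1", SaCLCa2 = "OM994378",
                SaCLCc1 = "MG670589.1", SaCLCc2 = "OM994379",
                SaCLCd = "OK626332.1", SaCLCf = "OK626333.1",
                SaCLCg = "OK626334.1")

args <- commandArgs(trailingOnly = TRUE)
out <- if (length(args)) args[1] else "saclc_proteins.fasta"

base <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
               "?db=nuccore&rettype=fasta_cds_aa&retmode=text&id=")
recs <- lapply(names(accessions), function(nm) {
  tmp <- tempfile(fileext = ".fa")
  utils::download.file(paste0(base, accessions[[nm]]), tmp, quiet = TRUE)
  r <- read_fasta(tmp, "protein")
  clc_seqs(nm, r$sequence[1], description = accessions[[nm]])
})
all <- do.call(rbind, lapply(recs, as.data.frame))
write_fasta(clc_seqs(all$id, all$sequence, all$description), out)
message("wrote ", out, "; run clcscan::check_table1('", out, "')")
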