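#!/usr/bin/env Rscript
# Geometry of the synthetic trimeric binding-site model.
#
# The model realizes the geometry described for the ion-bound receptor: the
# divalent ion in the gamma-only coordination mode (ion ~3.2 A from the
# gamma-phosphorus), coordinated by the D158 carboxylate, with E109 ~9 A
# away. This script measures all of that back through the parsing and
# classification pipeline and writes a per-site table.

suppressPackageStartupMessages(library(nucmet))

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
path <- file.path("scratch", "trimer_site_synthetic.pdb")
invisible(make_trimer_site_fixture(path))

model <- parse_structure(path)
print(model)
sites <- extract_sites(model)

rows <- lapply(sites, function(s) {
  ion <- select_bound_metal(s, "MG")
  res <- classify_mode(s, ion)
  pos <- as.numeric(ion[1, c("x", "y", "z")])
  gp <- as.numeric(s$gamma_phosphorus[1, c("x", "y", "z")])
  data.frame(
    chain = s$chain, mode = res$mode,
    N_a = res$N[["a"]], N_b = res$N[["b"]], N_g = res$N[["g"]],
    d2_gammaP_mg = sqrt(sum((pos - gp)^2)),
    mg_e109 = min_carboxylate_distance(model, pos, 109, s$chain),
    mg_d158 = min_carboxylate_distance(model, pos, 158, s$chain),
    mg_e156 = min_carboxylate_distance(model, pos, 156, s$chain),
    mg_e111 = min_carboxylate_distance(model, pos, 111, s$chain))
})
tab <- do.call(rbind, rows)
print(tab, digits = 4)
write.table(tab, file.path("results", "site_geometry.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("all three interfacial sites classify '", unique(tab$mode),
        "'; ion-to-E109 distance ", round(mean(tab$mg_e109), 2), " A")
message("table: results/site_geometry.tsv")
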