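#!/usr/bin/env Rscript
# Simulate the study conditions: 2D-equilibrated worm-like chains rendered
# as AFM-like height maps. Conditions: bare 1000 bp linear DNA (contour
# 328 nm, Lp 56 nm, imaged height 0.6 nm), the fully protein-coated
# filament after long incubation (contour 347 nm, height 1.0 nm), relaxed
# circular plasmid-scale DNA (contour 856 nm, closed), plus plectonemic and
# compacted morphologies for the topology stage.
#
# Writes float TIFFs + YAML sidecars, ground-truth CSV/JSON per condition
# under results/sim/<condition>/.

suppressMessages(library(afmwlc))
seed <- 20260401
out <- "results/sim"

conds <- list(bare = condition_bare_dna(12),
              coated = condition_coated_dna(12),
              circle = condition_relaxed_circle(10))
for (nm in names(conds)) {
  d <- file.path(out, nm)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  ens <- make_condition_ensemble(conds[[nm]], seed)
  for (i in seq_along(ens))
    write_afm_tiff(ens[[i]]$image, file.path(d, sprintf("mol%03d.tif", i)),
                   seed = seed)
  write_ground_truth(lapply(ens, `[[`, "polymer"),
                     file.path(d, "ground_truth.csv"),
                     file.path(d, "ground_truth.json"))
  message(sprintf("%s: %d molecules (Lp %g nm, contour %g nm, height %g nm)",
                  nm, length(ens), conds[[nm]]$lp_nm, conds[[nm]]$contour_nm,
                  conds[[nm]]$height_nm))
}

# topology fixtures: plectonemes (axis ratio 0.42 of an 860 nm circle) and
# compacted particles (45 x 17 nm rod at 1.5 nm)
d <- file.path(out, "plectoneme"); dir.create(d, showWarnings = FALSE)
pr <- render_params(ridge_height_nm = preblur_ridge_height(0.6))
truth <- list()
for (i in 1:5) {
  pl <- generate_plectoneme(860, 0.42, seed = seed + i, params = pr)
  write_afm_tiff(pl$image, file.path(d, sprintf("plect%02d.tif", i)),
                 seed = seed + i)
  truth[[i]] <- list(id = sprintf("plect%02d", i), axis_nm = pl$axis_nm,
                     contour_nm = pl$contour_nm)
}
write_report_json(truth, file.path(d, "truth.json"))
d <- file.path(out, "compact"); dir.create(d, showWarnings = FALSE)
for (i in 1:5) {
  cp <- generate_compact(seed = seed + i, params = pr)
  write_afm_tiff(cp$image, file.path(d, sprintf("compact%02d.tif", i)),
                 seed = seed + i)
}
message("simulation artifacts under ", out)
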