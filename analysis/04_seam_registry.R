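#!/usr/bin/env Rscript
# The seam/register reference grid of the pseudo-helical pipeline and the
# CKK binding sites it implies: a 13-pf microtubule needs 26 references
# (13 seam positions x 2 alpha/beta registers, each a distinct rigid
# transform), and CKK sites occupy every non-seam lateral junction once
# per dimer ring, 8 nm apart along the axis.

source("analysis/00_common.R")
opt <- analysis_args()
dir <- out_dir("seam")

for (N in c(13, 14)) {
  hyp <- enumerate_seam_hypotheses(lattice_spec(n_pf = N))
  write.csv(hyp, file.path(dir, sprintf("seam_hypotheses_%dpf.csv", N)),
            row.names = FALSE)
  cat(sprintf("%d-pf: %d seam/register references\n", N, nrow(hyp)))
}

lat <- build_lattice(lattice_spec(n_pf = 13, n_dimers = 3))
sites <- enumerate_binding_sites(lat)
write.csv(sites, file.path(dir, "binding_sites_13pf.csv"),
          row.names = FALSE)
spacing <- unlist(lapply(split(sites$z, sites$junction),
                         function(z) diff(sort(z))))
cat(sprintf(
  "13-pf: %d sites/ring (seam junction %d carries none), axial spacing %.1f A (~%d nm)\n",
  sum(sites$dimer == 0), lat$truth$seam_index, mean(spacing),
  round(mean(spacing) / 10)))
write_config(dir, list(seed = opt$seed))
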