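# two synthetic "methods" = two torsional potentials; the experimental
# table is fabricated from method A's ground truth, so A must win
build_study_dir <- function(dir) {
  tpl <- template_toy()
  pot_a <- torsional_potential(
    list(phi = list(center = 60, depth = 3, width = 15)))
  pot_b <- torsional_potential(
    list(phi = list(center = -170, depth = 3, width = 15)))
  sc <- saturation_scheme("H21", c("H11", "H12", "H13"), tpl$atoms)
  ens_a <- sample_ensemble(tpl, pot_a, n_frames = 1500, seed = 101)
  ens_b <- sample_ensemble(tpl, pot_b, n_frames = 1500, seed = 102)
  write_ensemble(ens_a, file.path(dir, "toy_A.pdb"))
  write_ensemble(ens_b, file.path(dir, "toy_B.pdb"))
  gt <- ground_truth(tpl, pot_a, sc, grid_step = 2)
  write_noe_table(gt$noe, file.path(dir, "toy_exp.tsv"))
  cfg <- list(
    molecules = list(list(
      name = "toy",
      trajectories = list(A = file.path(dir, "toy_A.pdb"),
                          B = file.path(dir, "toy_B.pdb")),
      saturation = list(list(saturated = "H21",
                             observed = list("H11", "H12", "H13"))),
      experimental_noe = file.path(dir, "toy_exp.tsv"),
      torsions = list(phi = list("C1", "O", "C2", "H21"))
    )),
    options = list(bin_width = 10)
  )
  yaml::write_yaml(cfg, file.path(dir, "study.yaml"))
  cfg
}
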