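# Shared fixtures: tiny hand-built molecules and ensembles.

# 4 non-exchangeable protons on a methane-like scaffold plus one hydroxyl;
# coordinates chosen so all H-H distances are distinct.
fix_atoms5 <- function() {
  atom_table(
    name = c("C1", "H1", "H2", "H3", "H4", "O1", "HO1"),
    element = c("C", "H", "H", "H", "H", "O", "H"),
    residue_index = c(1, 1, 1, 2, 2, 2, 2),
    exchangeable = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

fix_frame5 <- function() {
  rbind(
    c(0.0, 0.0, 0.0),    # C1
    c(1.1, 0.0, 0.0),    # H1
    c(0.0, 1.3, 0.0),    # H2
    c(0.0, 0.0, 1.7),    # H3
    c(1.0, 1.0, 1.0),    # H4
    c(-1.4, 0.0, 0.0),   # O1
    c(-1.8, 0.9, 0.0)    # HO1
  )
}

# random rigid motion: proper rotation from QR plus a shift
random_rigid <- function(frame, seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- rnorm(3, sd = 5)
  frame %*% t(R) + matrix(shift, nrow(frame), 3, byrow = TRUE)
}

# independent brute-force NOE: explicit loops, no shared code with frame_noe
oracle_noe <- function(frame, atoms, a, b) {
  hs <- which(atoms$element == "H" & !atoms$exchangeable) - 1L
  num <- sum((frame[a + 1L, ] - frame[b + 1L, ])^2)^(-3)
  den <- 0
  for (i in hs) {
    if (i != a) den <- den + sum((frame[a + 1L, ] - frame[i + 1L, ])^2)^(-3)
  }
  num / (2 * den)
}

# minimal torsion_series wrapper around a raw angle matrix
fake_series <- function(values) {
  values <- as.matrix(values)
  defs <- lapply(colnames(values), function(lab) {
    structure(list(label = lab, atom_quad = 0:3),
              class = "torsion_definition")
  })
  structure(list(definitions = defs, values = values),
            class = "torsion_series")
}

# blob ensembles: frames scattered around k reference geometries that
# differ in internal structure (not mere rigid motion), so alignment
# preserves separation
blob_ensemble <- function(n_per, centers_scale = 6, sd = 0.05, seed = 21,
                          natoms = 4) {
  set.seed(seed)
  k <- length(n_per)
  refs <- lapply(seq_len(k), function(i) {
    matrix(rnorm(natoms * 3, sd = centers_scale), natoms, 3)
  })
  frames <- list(); labels <- integer(0)
  for (i in seq_len(k)) {
    for (j in seq_len(n_per[i])) {
      f <- refs[[i]] + matrix(rnorm(natoms * 3, sd = sd), natoms, 3)
      frames[[length(frames) + 1L]] <- random_rigid(f, seed * 1000 + i * 97 + j)
      labels <- c(labels, i)
    }
  }
  atoms <- atom_table(paste0("C", seq_len(natoms)), rep("C", natoms),
                      rep(1, natoms))
  list(ens = ensemble(atoms, frames), labels = labels)
}
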