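# Independent oracles used across the suite.

# O(L^2) double-loop contact counter, written independently of
# contact_number_profile()
brute_force_contacts <- function(pos, cutoff = 7.5, cap = 14) {
  L <- nrow(pos)
  raw <- numeric(L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (abs(j - i) > 2) {
        d <- sqrt((pos[i, 1] - pos[j, 1])^2 + (pos[i, 2] - pos[j, 2])^2 +
                    (pos[i, 3] - pos[j, 3])^2)
        if (d < cutoff) raw[i] <- raw[i] + 1
      }
    }
  }
  list(raw = raw, labels = pmin(raw, cap))
}

# central-difference gradient of sparse_cost over one parameter block
numeric_layer_gradient <- function(layer, X, block, mask = NULL, eps = 1e-5) {
  v0 <- layer[[block]]
  g <- v0
  for (i in seq_along(v0)) {
    lp <- layer; lp[[block]][i] <- v0[i] + eps
    lm <- layer; lm[[block]][i] <- v0[i] - eps
    g[i] <- (sparse_cost(lp, X, mask) - sparse_cost(lm, X, mask)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b, floor = 1e-8) {
  max(abs(a - b) / pmax(abs(a), abs(b), floor))
}

# central-difference gradient of the fine-tuning objective
numeric_finetune_gradient <- function(model, X, y, eps = 1e-5) {
  p0 <- model_parameters(model)
  g <- p0
  for (i in seq_along(p0)) {
    pp <- p0; pp[i] <- pp[i] + eps
    pm <- p0; pm[i] <- pm[i] - eps
    g[i] <- (finetune_objective(set_model_parameters(model, pp), X, y) -
               finetune_objective(set_model_parameters(model, pm), X, y)) /
      (2 * eps)
  }
  g
}

sa3_to_int <- function(labels) match(labels, c("B", "I", "E")) - 1L

# small protein fixture bundle: structure, profiles, tracks, dssp
make_protein_fixture <- function(L = 20, seed = 1, dir = tempfile()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- fixture_spec(L, seed, "random_coil", noise_sd = 0.2)
  st <- generate_structure(spec, file.path(dir, "prot.pdb"))
  sq <- st$coords$sequence
  writeLines(c(">prot", sq), file.path(dir, "prot.fasta"))
  pr <- generate_profiles(sq, seed + 1, dir)
  tk <- generate_structure_tracks(sq, seed + 2, dir)
  dp <- generate_dssp(sq, seed + 3, file.path(dir, "prot.dssp"))
  list(dir = dir, sequence = sq, structure = st, profiles = pr,
       tracks = tk, dssp = dp,
       fasta = file.path(dir, "prot.fasta"))
}
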