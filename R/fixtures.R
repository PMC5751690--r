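#' Specification for a synthetic structure fixture
#'
#' The fixture generators emulate the *shape* of the real input formats and
#' the statistical structure needed for testing; they are not biologically
#' realistic (see the methods vignette).
#'
#' @param n_residues chain length (>= 1).
#' @param rng_seed integer seed; all generator randomness derives from it.
#' @param geometry `"ideal_helix"` (rise 1.5 A, twist 100 deg, radius
#'   2.3 A), `"random_coil"` (3.8 A step random walk) or
#'   `"compact_cluster"` (uniform in a 2.5 A-radius ball).
#' @param noise_sd isotropic Gaussian positional noise, Angstroms.
#' @param class_separation mean separation for labeled feature sets.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues, rng_seed = 1L,
                         geometry = c("ideal_helix", "random_coil",
                                      "compact_cluster"),
                         noise_sd = 0, class_separation = 0) {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 1, noise_sd >= 0, class_separation >= 0)
  structure(list(n_residues = as.integer(n_residues),
                 rng_seed = as.integer(rng_seed), geometry = geometry,
                 noise_sd = noise_sd, class_separation = class_separation),
            class = "fixture_spec")
}

# seeded random sequence over the 20 standard residues
.random_sequence <- function(n) {
  paste(sample(canonical_residues(), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic structure and optional PDB file
#'
#' Places contact atoms according to the spec geometry, adds seeded
#' Gaussian noise, and (when `path` is given) writes a PDB file with CA and
#' CB atoms such that reading it back with [read_pdb_coordinates()]
#' recovers the generated contact-atom positions (CB, or CA for glycine)
#' to PDB column precision.
#'
#' @param spec a [fixture_spec()].
#' @param path optional PDB output path.
#' @param chain chain identifier for the written file.
#' @param sequence optional one-letter sequence; random by default.
#' @return List with `coords` (a `residue_coordinates` carrying
#'   `$sequence`) and `path` (NULL if not written).
#' @export
generate_structure <- function(spec, path = NULL, chain = "A",
                               sequence = NULL) {
  set.seed(spec$rng_seed)
  n <- spec$n_residues
  if (is.null(sequence)) sequence <- .random_sequence(n)
  stopifnot(nchar(sequence) == n)
  pos <- switch(spec$geometry,
    ideal_helix = {
      i <- seq_len(n) - 1
      theta <- i * 100 * pi / 180
      cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
    },
    random_coil = {
      steps <- matrix(stats::rnorm(3 * n), n, 3)
      steps <- steps / sqrt(rowSums(steps^2)) * 3.8
      steps[1, ] <- 0
      apply(steps, 2, cumsum)
    },
    compact_cluster = {
      p <- matrix(stats::rnorm(3 * n), n, 3)
      u <- stats::runif(n)^(1 / 3) * 2.5
      p / sqrt(rowSums(p^2)) * u
    })
  pos <- matrix(pos, n, 3)
  if (spec$noise_sd > 0)
    pos <- pos + matrix(stats::rnorm(3 * n, sd = spec$noise_sd), n, 3)
  coords <- residue_coordinates(pos)
  coords$sequence <- sequence
  if (!is.null(path)) .write_fixture_pdb(coords, path, chain)
  list(coords = coords, path = path)
}

# PDB writer for fixtures: CB carries the contact-atom position (CA for
# glycine); CA sits 1.5 A away so both atoms exist for non-GLY residues.
.write_fixture_pdb <- function(coords, path, chain = "A") {
  res <- strsplit(coords$sequence, "")[[1]]
  lines <- character(0)
  serial <- 0L
  atom_line <- function(serial, name, res3, chain, resno, xyz) {
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, paste0(" ", name), res3, chain, resno,
            xyz[1], xyz[2], xyz[3])
  }
  for (i in seq_along(res)) {
    res3 <- .aa_one_to_three[[res[i]]]
    p <- coords$positions[i, ]
    if (res[i] == "G") {
      serial <- serial + 1L
      lines <- c(lines, atom_line(serial, "CA", res3, chain, i, p))
    } else {
      serial <- serial + 1L
      lines <- c(lines, atom_line(serial, "CA", res3, chain, i, p + c(1.5, 0, 0)))
      serial <- serial + 1L
      lines <- c(lines, atom_line(serial, "CB", res3, chain, i, p))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate synthetic PSSM and HHM profile files
#'
#' The PSSM mimics the PSI-BLAST ASCII layout: integer log-odds in
#' `[-10, 10]` with the true residue's own column biased by +5, plus the
#' trailing percentage columns real files carry.  The HHM mimics the
#' HHblits .hhm layout with match-emission probabilities encoded as
#' `round(-1000 * log2(p))` (probability-0 entries written as `*`).
#'
#' @param sequence one-letter amino-acid string.
#' @param seed integer seed.
#' @param dir output directory (created if absent).
#' @return List with `pssm_path`, `hhm_path`, and the generating matrices
#'   `pssm` (integers, canonical column order) and `hhm` (decoded
#'   probabilities actually representable in the file encoding).
#' @export
generate_profiles <- function(sequence, seed = 1L, dir = tempdir()) {
  set.seed(seed)
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  aa <- canonical_residues()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  pssm <- matrix(sample(-10:10, L * 20, replace = TRUE), L, 20,
                 dimnames = list(NULL, aa))
  for (i in seq_len(L)) if (res[i] %in% aa)
    pssm[i, res[i]] <- pssm[i, res[i]] + 5L
  pssm_path <- file.path(dir, "fixture.pssm")
  hdr <- paste0("Last position-specific scoring matrix computed, ",
                "weighted observed percentages rounded down")
  col_hdr <- paste0("          ", paste(sprintf("%4s", aa), collapse = ""),
                    " ", paste(sprintf("%4s", aa), collapse = ""))
  rows <- vapply(seq_len(L), function(i) {
    paste0(sprintf("%5d %s ", i, res[i]),
           paste(sprintf("%4d", pssm[i, ]), collapse = ""), " ",
           paste(sprintf("%4d", sample(0:99, 20, replace = TRUE)), collapse = ""))
  }, "")
  writeLines(c("", hdr, col_hdr, rows, "", "                      K         Lambda"),
             pssm_path)

  hhm_alpha <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  raw <- matrix(stats::rgamma(L * 20, shape = 0.5), L, 20)
  prob <- raw / rowSums(raw) * 0.9          # rows sum to <= 1
  prob[prob < 2^(-20)] <- 0                 # below encodable range -> '*'
  s <- ifelse(prob == 0, NA, round(-1000 * log2(prob)))
  decoded <- ifelse(is.na(s), 0, 2^(-s / 1000))
  colnames(decoded) <- hhm_alpha
  hhm_path <- file.path(dir, "fixture.hhm")
  lines <- c("HHsearch 1.5", "NAME  fixture", paste0("LENG  ", L), "",
             paste(c("HMM", hhm_alpha), collapse = "\t"),
             paste(c("", "M->M", "M->I", "M->D", "I->M", "I->I",
                     "D->M", "D->D", "Neff"), collapse = "\t"))
  for (i in seq_len(L)) {
    enc <- ifelse(is.na(s[i, ]), "*", as.character(s[i, ]))
    lines <- c(lines,
               paste(c(res[i], i, enc, i), collapse = "\t"),
               paste(c("", "0", "*", "*", "*", "*", "*", "*", "1000"),
                     collapse = "\t"),
               "")
  }
  writeLines(c(lines, "//"), hhm_path)

  list(pssm_path = pssm_path, hhm_path = hhm_path,
       pssm = pssm, hhm = decoded)
}

# quantize a probability row to 6 decimals so the written values still sum
# to exactly 1 at file precision
.quantize_simplex <- function(p) {
  q <- round(p[-length(p)], 6)
  c(q, 1 - sum(q))
}

#' Generate synthetic predicted-structure track files
#'
#' Writes a PSIPRED-style .ss2 file (Dirichlet-like per-residue
#' probabilities summing to 1 at file precision), a disorder table and a
#' backbone-angle table, all parseable by the corresponding readers.
#'
#' @param sequence one-letter amino-acid string.
#' @param seed integer seed.
#' @param dir output directory.
#' @return List with `ss2_path`, `disorder_path`, `angles_path` and the
#'   generating matrices `ss` (helix/strand/coil order), `disorder`,
#'   `angles` as representable at file precision.
#' @export
generate_structure_tracks <- function(sequence, seed = 1L, dir = tempdir()) {
  set.seed(seed)
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  ss <- t(vapply(seq_len(L), function(i) {
    g <- stats::rgamma(3, shape = 1)
    .quantize_simplex(g / sum(g))
  }, numeric(3)))
  colnames(ss) <- c("helix", "strand", "coil")
  ss2_path <- file.path(dir, "fixture.ss2")
  state <- c("H", "E", "C")[max.col(ss, ties.method = "first")]
  rows <- sprintf("%4d %s %s  %8.6f %8.6f %8.6f", seq_len(L), res, state,
                  ss[, "coil"], ss[, "helix"], ss[, "strand"])
  writeLines(c("# PSIPRED VFORMAT (PSIPRED V4.0)", "", rows), ss2_path)

  pdis <- round(stats::runif(L), 6)
  dis <- cbind(disordered = pdis, ordered = 1 - pdis)
  disorder_path <- file.path(dir, "fixture.diso")
  writeLines(c("# residue disorder probabilities",
               sprintf("%4d %s %8.6f %8.6f", seq_len(L), res,
                       dis[, 1], dis[, 2])), disorder_path)

  ang <- matrix(round(stats::runif(4 * L, -180, 180), 2), L, 4)
  angles_path <- file.path(dir, "fixture.angles")
  writeLines(c("# residue backbone angle features",
               sprintf("%4d %s %9.2f %9.2f %9.2f %9.2f", seq_len(L), res,
                       ang[, 1], ang[, 2], ang[, 3], ang[, 4])), angles_path)

  list(ss2_path = ss2_path, disorder_path = disorder_path,
       angles_path = angles_path, ss = ss, disorder = dis, angles = ang)
}

#' Generate a DSSP-style file with a synthetic ACC column
#'
#' ACC values are seeded uniform integers in `[0, maxASA(type)]`, so every
#' derived RSA lies in `[0, 1]`.
#'
#' @param sequence one-letter amino-acid string.
#' @param seed integer seed.
#' @param path output file path.
#' @param chain chain identifier.
#' @return List with `path` and the generating `acc` integer vector.
#' @export
generate_dssp <- function(sequence, seed = 1L,
                          path = tempfile(fileext = ".dssp"), chain = "A") {
  set.seed(seed)
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  maxasa <- max_asa_table()
  denom <- ifelse(res == "X", mean(maxasa), maxasa[res])
  acc <- vapply(denom, function(m) sample.int(floor(m) + 1L, 1L) - 1L, 0L)
  rows <- sprintf("%5d%5d %s %s%20s%4d", seq_len(L), seq_len(L), chain, res,
                  "", acc)
  writeLines(c("==== Secondary Structure Definition (synthetic fixture) ====",
               "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
               rows), path)
  list(path = path, acc = acc)
}

#' Generate a separable labeled feature dataset
#'
#' Balanced class-conditional Gaussian blobs with unit variance; class k's
#' mean is `class_separation` along the k-th coordinate direction (cycled
#' when classes outnumber features).
#'
#' @param n_samples total rows (split as evenly as possible).
#' @param n_features feature dimension.
#' @param n_classes number of classes (>= 2).
#' @param class_separation distance scale between class means.
#' @param seed integer seed.
#' @return List with `X` (n x d matrix) and `y` (0-based integer labels).
#' @export
generate_labeled_dataset <- function(n_samples, n_features, n_classes,
                                     class_separation, seed = 1L) {
  stopifnot(n_classes >= 2)
  set.seed(seed)
  per <- diff(round(seq(0, n_samples, length.out = n_classes + 1)))
  y <- rep(seq_len(n_classes) - 1L, per)
  X <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
  for (k in seq_len(n_classes)) {
    dim_k <- ((k - 1L) %% n_features) + 1L
    X[y == k - 1L, dim_k] <- X[y == k - 1L, dim_k] + class_separation
  }
  ord <- sample.int(n_samples)
  list(X = X[ord, , drop = FALSE], y = y[ord])
}
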