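#' Logistic normalisation of profile values
#'
#' Maps a raw profile score `x` to `1 / (1 + exp(-x))`, the standard
#' logistic squashing used to bring PSSM log-odds (and, for uniformity,
#' HMM emission probabilities) into `(0, 1)`.
#'
#' @param x numeric vector/matrix of finite raw values.
#' @return Same shape as `x`, values in `(0, 1)`.
#' @export
logistic_normalize <- function(x) {
  stopifnot(all(is.finite(x)))
  sigmoid(x)
}

#' Evolutionary feature block (40 columns)
#'
#' Columns 1-20 are the logistic-normalised PSSM log-odds, columns 21-40
#' the logistic-normalised HMM emission probabilities, both reconciled to
#' the canonical residue column order first so any input column permutation
#' yields identical features.
#'
#' @param pssm `profile_matrix` of kind `"pssm"`.
#' @param hhm `profile_matrix` of kind `"hhm"`.
#' @return L x 40 numeric matrix.
#' @export
build_evolution_block <- function(pssm, hhm) {
  stopifnot(inherits(pssm, "profile_matrix"), pssm$kind == "pssm",
            inherits(hhm, "profile_matrix"), hhm$kind == "hhm")
  if (nrow(pssm$values) != nrow(hhm$values))
    stop("alignment error: PSSM has ", nrow(pssm$values),
         " rows but HHM has ", nrow(hhm$values))
  aa <- canonical_residues()
  p <- pssm$values[, aa, drop = FALSE]
  h <- hhm$values[, aa, drop = FALSE]
  out <- cbind(logistic_normalize(p), logistic_normalize(h))
  colnames(out) <- c(paste0("pssm_", aa), paste0("hhm_", aa))
  out
}

#' Structural feature block (9 columns)
#'
#' Concatenates secondary-structure probabilities (3), disorder
#' probabilities (2) and backbone-angle features (4).  Probabilities pass
#' through unchanged; angle columns are min-max scaled to `[0, 1]` over the
#' chain (a constant column maps to 0.5).
#'
#' @param track a `structure_feature_track`.
#' @return L x 9 numeric matrix.
#' @export
build_structure_block <- function(track) {
  stopifnot(inherits(track, "structure_feature_track"))
  ang <- apply(track$backbone_angles, 2, function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0.5, length(v)) else (v - r[1]) / diff(r)
  })
  ang <- matrix(ang, nrow = nrow(track$backbone_angles))
  out <- cbind(track$ss_probs, track$disorder, ang)
  colnames(out) <- c("helix", "strand", "coil", "disordered", "ordered",
                     paste0("angle", 1:4))
  out
}

#' Amino-acid feature block (27 columns)
#'
#' Position-independent lookup per residue type: the 20 contact-potential
#' values followed by the 7 physicochemical properties.  Unknown residues
#' (`X`) use the column-wise mean of the table.
#'
#' @param sequence one-letter amino-acid string.
#' @param table an [amino_acid_table()].
#' @return L x 27 numeric matrix.
#' @export
build_amino_acid_block <- function(sequence, table = amino_acid_table()) {
  stopifnot(inherits(table, "amino_acid_table"))
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(res), c(canonical_residues(), "X"))
  if (length(bad))
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  full <- cbind(table$contact_potential, table$physicochemical)
  xrow <- colMeans(full)
  out <- t(vapply(res, function(a) if (a == "X") xrow else full[a, ],
                  numeric(27)))
  rownames(out) <- NULL
  colnames(out) <- c(paste0("cp_", canonical_residues()),
                     colnames(table$physicochemical))
  out
}

#' Assemble the full 76-column per-residue feature table
#'
#' Block order is evolution (40), structure (9), amino acid (27).
#'
#' @param pssm,hhm profile matrices (see [build_evolution_block()]).
#' @param track a `structure_feature_track`.
#' @param sequence one-letter amino-acid string.
#' @param table an [amino_acid_table()].
#' @return Object of class `feature_table`: L x 76 `matrix` plus
#'   `block_spans` naming the column range of each block.
#' @export
build_feature_table <- function(pssm, hhm, track, sequence,
                                table = amino_acid_table()) {
  evo <- build_evolution_block(pssm, hhm)
  str <- build_structure_block(track)
  aab <- build_amino_acid_block(sequence, table)
  L <- nchar(sequence)
  if (nrow(evo) != L || nrow(str) != L)
    stop("alignment error: feature blocks disagree with sequence length ", L)
  structure(list(matrix = cbind(evo, str, aab),
                 block_spans = list(evolution = 1:40, structure = 41:49,
                                    amino_acid = 50:76)),
            class = "feature_table")
}

#' Sliding-window expansion of per-residue features
#'
#' Row i of the result concatenates feature rows `i-(w-1)/2 .. i+(w-1)/2`;
#' window positions beyond either terminus contribute zero vectors.  At the
#' default window 11 over 76 features each row has width 836.
#'
#' @param features a `feature_table` or plain L x d matrix.
#' @param w odd window size (default 11).
#' @return Object of class `window_matrix`: `matrix` of size L x (d*w),
#'   `window_size`, and `padding = "zero"`.
#' @export
slide_window <- function(features, w = 11L) {
  m <- if (inherits(features, "feature_table")) features$matrix else as.matrix(features)
  w <- as.integer(w)
  if (w %% 2L == 0L) stop("window size must be odd, got ", w)
  stopifnot(w >= 1L)
  L <- nrow(m); d <- ncol(m); half <- (w - 1L) %/% 2L
  out <- matrix(0, L, d * w)
  for (k in seq_len(w)) {
    off <- k - 1L - half
    src <- seq_len(L) + off
    ok <- src >= 1L & src <= L
    cols <- ((k - 1L) * d + 1L):(k * d)
    out[ok, cols] <- m[src[ok], , drop = FALSE]
  }
  structure(list(matrix = out, window_size = w, padding = "zero"),
            class = "window_matrix")
}
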