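#' Protein record
#'
#' @param id chain identifier string.
#' @param sequence one-letter amino-acid string (20 standard codes plus
#'   `X` for unknown).
#' @param source_path provenance string.
#' @return Object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, source_path = NA_character_) {
  stopifnot(nchar(sequence) > 0)
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]),
                 c(canonical_residues(), "X"))
  if (length(bad))
    stop("invalid residue letter(s) in sequence: ", paste(bad, collapse = ", "))
  structure(list(id = id, sequence = sequence, source_path = source_path),
            class = "protein_record")
}

#' Profile matrix (PSSM or HMM emissions)
#'
#' @param kind `"pssm"` (raw log-odds) or `"hhm"` (emission probabilities).
#' @param values L x 20 numeric matrix in raw file units.
#' @param alphabet_order 20-residue column ordering as read from the file.
#' @return Object of class `profile_matrix`.
#' @export
profile_matrix <- function(kind = c("pssm", "hhm"), values, alphabet_order) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  stopifnot(ncol(values) == 20, length(alphabet_order) == 20,
            setequal(alphabet_order, canonical_residues()))
  if (kind == "hhm" && any(values < 0 | values > 1))
    stop("HMM emission probabilities must lie in [0, 1]")
  colnames(values) <- alphabet_order
  structure(list(kind = kind, values = values, alphabet_order = alphabet_order),
            class = "profile_matrix")
}

#' Predicted structure feature track
#'
#' @param ss_probs L x 3 matrix of secondary-structure probabilities in
#'   helix / strand / coil order.
#' @param disorder L x 2 matrix of disorder probabilities.
#' @param backbone_angles L x 4 matrix of predicted backbone-angle features.
#' @return Object of class `structure_feature_track`.
#' @export
structure_feature_track <- function(ss_probs, disorder, backbone_angles) {
  ss_probs <- as.matrix(ss_probs); disorder <- as.matrix(disorder)
  backbone_angles <- as.matrix(backbone_angles)
  L <- nrow(ss_probs)
  if (nrow(disorder) != L || nrow(backbone_angles) != L)
    stop("structure feature blocks disagree on length: ss=", L,
         " disorder=", nrow(disorder), " angles=", nrow(backbone_angles))
  stopifnot(ncol(ss_probs) == 3, ncol(disorder) == 2, ncol(backbone_angles) == 4)
  if (any(ss_probs < 0 | ss_probs > 1) || any(disorder < 0 | disorder > 1))
    stop("probabilities outside [0, 1] in structure feature track")
  structure(list(ss_probs = ss_probs, disorder = disorder,
                 backbone_angles = backbone_angles),
            class = "structure_feature_track")
}

#' Absolute solvent accessibility track
#'
#' @param asa numeric vector of non-negative per-residue ASA values in
#'   square Angstroms.
#' @return Object of class `asa_track`.
#' @export
asa_track <- function(asa) {
  stopifnot(all(asa >= 0, na.rm = TRUE))
  structure(list(asa = as.numeric(asa)), class = "asa_track")
}

#' Read per-residue contact-atom coordinates from a PDB file
#'
#' Parses ATOM records of one chain (first model, first altloc) and takes
#' the CB atom position per residue, falling back to CA for glycine or
#' whenever CB is absent.  Residues with neither atom are flagged missing.
#'
#' @param path PDB file path.
#' @param chain chain identifier.
#' @return A `residue_coordinates` object with an additional `sequence`
#'   element (one-letter codes, `X` for non-standard residues).
#' @export
read_pdb_coordinates <- function(path, chain = "A") {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", chain, "' not found in ", path)
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  # residue identity = (resno, insert) in file order
  key <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  res_keys <- unique(key)
  L <- length(res_keys)
  pos <- matrix(NA_real_, L, 3)
  miss <- rep(FALSE, L)
  seq_chr <- character(L)
  for (k in seq_len(L)) {
    rows <- at[key == res_keys[k], , drop = FALSE]
    resname <- rows$resid[1]
    seq_chr[k] <- if (resname %in% names(.aa_three_to_one))
      .aa_three_to_one[[resname]] else "X"
    pick <- rows[rows$elety == "CB", , drop = FALSE]
    if (nrow(pick) == 0) pick <- rows[rows$elety == "CA", , drop = FALSE]
    if (nrow(pick) == 0) {
      miss[k] <- TRUE
    } else {
      pos[k, ] <- as.numeric(pick[1, c("x", "y", "z")])
    }
  }
  if (all(miss)) stop("no resolvable CB/CA atoms in chain '", chain, "'")
  out <- residue_coordinates(pos, miss)
  out$sequence <- paste(seq_chr, collapse = "")
  out
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Keeps the first 20 score columns (position-specific log-odds) of each
#' residue row; residue order is preserved and the column alphabet is taken
#' from the file header.
#'
#' @param path PSSM file path.
#' @return A `profile_matrix` with `kind = "pssm"`.
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  # header: first line whose tokens are >= 20 single residue letters
  alpha <- NULL
  for (tk in toks) {
    if (length(tk) >= 20 && all(nchar(tk) == 1) &&
        setequal(unique(tk[1:20]), intersect(tk[1:20], canonical_residues())) &&
        length(unique(tk[1:20])) == 20) {
      alpha <- tk[1:20]
      break
    }
  }
  if (is.null(alpha)) alpha <- canonical_residues()
  is_data <- grepl("^\\s*\\d+\\s+[A-Z]", lines)
  if (!any(is_data)) stop("no residue rows found in PSSM file: ", path)
  rows <- list(); res <- character(0)
  for (i in which(is_data)) {
    tk <- toks[[i]]
    vals <- suppressWarnings(as.numeric(tk[-(1:2)]))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 20)
      stop("malformed PSSM row at line ", i, ": expected 20 score columns, got ",
           length(vals))
    rows[[length(rows) + 1L]] <- vals[1:20]
    res <- c(res, tk[2])
  }
  m <- do.call(rbind, rows)
  rownames(m) <- NULL
  out <- profile_matrix("pssm", m, alpha)
  out$sequence <- paste(res, collapse = "")
  out
}

#' Read an HHblits .hhm profile
#'
#' Extracts the 20 match-state emission probabilities per residue from the
#' HMM block.  Stored integers `s` decode as `2^(-s/1000)`; the `*`
#' sentinel decodes to probability 0.
#'
#' @param path .hhm file path.
#' @return A `profile_matrix` with `kind = "hhm"` (values in `[0, 1]`).
#' @export
read_hhm <- function(path) {
  if (!file.exists(path)) stop("HHM file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^HMM\\s", lines)
  if (length(hdr) == 0) stop("no HMM block found in ", path)
  hdr <- hdr[1]
  alpha <- strsplit(trimws(sub("^HMM", "", lines[hdr])), "\\s+")[[1]]
  alpha <- alpha[nchar(alpha) == 1][1:20]
  rows <- list(); res <- character(0)
  i <- hdr + 1L
  while (i <= length(lines)) {
    l <- lines[i]
    if (grepl("^//", l)) break
    tk <- strsplit(trimws(l), "\\s+")[[1]]
    # match-emission line: residue letter, position, 20 values, position
    if (length(tk) >= 22 && nchar(tk[1]) == 1 && tk[1] %in% c(canonical_residues(), "X") &&
        grepl("^\\d+$", tk[2])) {
      s <- tk[3:22]
      p <- ifelse(s == "*", 0, 2^(-suppressWarnings(as.numeric(s)) / 1000))
      if (any(is.na(p))) stop("malformed HHM emission line ", i)
      rows[[length(rows) + 1L]] <- p
      res <- c(res, tk[1])
    }
    i <- i + 1L
  }
  if (length(rows) == 0) stop("no match-state emission lines in HMM block of ", path)
  out <- profile_matrix("hhm", do.call(rbind, rows), alpha)
  out$sequence <- paste(res, collapse = "")
  out
}

#' Read a PSIPRED .ss2 secondary-structure file
#'
#' @param path .ss2 file path (columns: index, residue, state letter, then
#'   coil / helix / strand probabilities).
#' @param expected_length optional sequence length to validate against.
#' @return L x 3 matrix of probabilities in helix / strand / coil order.
#' @export
read_psipred_ss2 <- function(path, expected_length = NULL) {
  rows <- .read_track_rows(path, n_values = 3)
  m <- rows$values[, c(2, 3, 1), drop = FALSE]  # file C,H,E -> internal H,E,C
  colnames(m) <- c("helix", "strand", "coil")
  if (any(m < 0 | m > 1))
    stop("secondary-structure probabilities outside [0, 1] in ", path)
  .check_track_length(nrow(m), expected_length, path)
  m
}

#' Read a per-residue disorder probability table
#'
#' @param path two-value-per-residue table (index, residue, P(disordered),
#'   P(ordered)).
#' @param expected_length optional sequence length to validate against.
#' @return L x 2 matrix of probabilities.
#' @export
read_disorder <- function(path, expected_length = NULL) {
  rows <- .read_track_rows(path, n_values = 2)
  m <- rows$values
  colnames(m) <- c("disordered", "ordered")
  if (any(m < 0 | m > 1)) stop("disorder probabilities outside [0, 1] in ", path)
  .check_track_length(nrow(m), expected_length, path)
  m
}

#' Read a per-residue backbone-angle feature table
#'
#' @param path four-value-per-residue table (index, residue, 4 angle
#'   features).
#' @param expected_length optional sequence length to validate against.
#' @return L x 4 numeric matrix.
#' @export
read_backbone_angles <- function(path, expected_length = NULL) {
  rows <- .read_track_rows(path, n_values = 4)
  m <- rows$values
  colnames(m) <- paste0("angle", 1:4)
  .check_track_length(nrow(m), expected_length, path)
  m
}

# shared column-table reader: index, residue letter, n_values numbers
.read_track_rows <- function(path, n_values) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- grepl("^\\s*\\d+\\s+[A-Z]", lines)
  if (!any(keep)) stop("no residue rows found in ", path)
  vals <- matrix(NA_real_, sum(keep), n_values)
  res <- character(sum(keep))
  r <- 0L
  for (i in which(keep)) {
    tk <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(tk))
    num <- num[!is.na(num)][-1]  # drop the leading residue index
    if (length(num) < n_values)
      stop("malformed row at line ", i, " of ", path, ": expected ",
           n_values, " values, got ", length(num))
    r <- r + 1L
    vals[r, ] <- num[1:n_values]
    res[r] <- tk[2]
  }
  list(values = vals, residues = res)
}

.check_track_length <- function(got, expected, path) {
  if (!is.null(expected) && got != expected)
    stop("alignment error: ", path, " has ", got,
         " residue rows but the sequence has length ", expected)
  invisible(TRUE)
}

#' Read per-residue ASA from a DSSP output file
#'
#' Parses the fixed-column DSSP layout, keeps rows of the requested chain
#' in sequence order, skips chain-break markers, and returns the ACC
#' column.
#'
#' @param path DSSP output file path.
#' @param chain chain identifier.
#' @return An `asa_track`.
#' @export
read_dssp_asa <- function(path, chain = "A") {
  if (!file.exists(path)) stop("DSSP file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^\\s+#\\s+RESIDUE", lines)
  if (length(hdr) == 0) stop("no residue table header in DSSP file: ", path)
  body <- lines[(hdr[1] + 1L):length(lines)]
  body <- body[nchar(body) >= 38]
  aa <- substr(body, 14, 14)
  ch <- substr(body, 12, 12)
  body <- body[aa != "!"]; ch2 <- ch[aa != "!"]
  sel <- ch2 == chain
  if (!any(sel)) stop("chain '", chain, "' not present in DSSP file: ", path)
  acc_txt <- substr(body[sel], 35, 38)
  blank <- grepl("^\\s*$", acc_txt)
  if (any(blank))
    stop("blank ACC column at residue ", which(blank)[1], " of chain ", chain)
  acc <- as.numeric(acc_txt)
  if (any(is.na(acc))) stop("unparseable ACC value in DSSP file: ", path)
  if (any(acc < 0)) stop("negative ACC value at residue ", which(acc < 0)[1])
  asa_track(acc)
}

#' Write per-residue predictions to TSV
#'
#' Tab-separated output with one data row per residue: 1-based index,
#' residue letter, predicted label and the per-class probabilities.  The
#' header line identifies the task.
#'
#' @param record a `protein_record`.
#' @param labels a `label_track` aligned to the sequence.
#' @param probs L x M matrix of class probabilities (rows sum to 1).
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_predictions <- function(record, labels, probs, path) {
  res <- strsplit(record$sequence, "")[[1]]
  probs <- as.matrix(probs)
  if (length(labels$labels) != length(res) || nrow(probs) != length(res))
    stop("labels/probabilities not aligned to sequence (L=", length(res), ")")
  cls <- .class_names(labels$task, ncol(probs))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# task=", labels$task, " classes=",
                    paste(cls, collapse = ",")), con)
  writeLines(paste(c("index", "residue", "label", paste0("p_", cls)),
                   collapse = "\t"), con)
  for (i in seq_along(res)) {
    writeLines(paste(c(i, res[i], as.character(labels$labels[i]),
                       sprintf("%.6f", probs[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read back a predictions TSV written by [write_predictions()]
#'
#' @param path prediction file path.
#' @return List with `task`, `labels` (a `label_track`), `probs` matrix and
#'   `sequence`.
#' @export
read_predictions <- function(path) {
  lines <- readLines(path)
  task <- sub("^# task=(\\S+).*$", "\\1", lines[1])
  df <- utils::read.delim(text = lines[-1], check.names = FALSE)
  probs <- as.matrix(df[, grep("^p_", names(df)), drop = FALSE])
  labels <- if (task == "cn15") as.integer(df$label) else as.character(df$label)
  list(task = task,
       labels = label_track(task, labels),
       probs = probs,
       sequence = paste(df$residue, collapse = ""))
}

.class_names <- function(task, m) {
  if (task == "sa3") {
    stopifnot(m == 3); c("B", "I", "E")
  } else {
    as.character(seq_len(m) - 1L)
  }
}
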