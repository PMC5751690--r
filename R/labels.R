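#' Configuration for contact-number labelling
#'
#' @param cutoff_radius sphere radius in Angstroms around the contact atom;
#'   default 7.5.
#' @param sequence_separation_min minimum sequence separation; residue pairs
#'   with `abs(j - i) <= sequence_separation_min - 1` are never counted.  The
#'   default 3 means only pairs with `|j - i| > 2` qualify.
#' @param cap raw counts above this value collapse to it, so labels span
#'   `0..cap` (15 states at the default 14).
#' @return Object of class `contact_config`.
#' @export
contact_config <- function(cutoff_radius = 7.5, sequence_separation_min = 3,
                           cap = 14L) {
  stopifnot(cutoff_radius > 0, cap >= 1, sequence_separation_min >= 1)
  structure(list(cutoff_radius = cutoff_radius,
                 sequence_separation_min = as.integer(sequence_separation_min),
                 cap = as.integer(cap)),
            class = "contact_config")
}

#' Configuration for three-state solvent accessibility
#'
#' @param threshold_bi RSA fraction separating buried from intermediate
#'   (default 0.10).
#' @param threshold_ie RSA fraction separating intermediate from exposed
#'   (default 0.40).
#' @param max_asa_table named numeric vector of per-residue maximum ASA in
#'   square Angstroms; defaults to [max_asa_table()].
#' @return Object of class `solvent_config`.
#' @export
solvent_config <- function(threshold_bi = 0.10, threshold_ie = 0.40,
                           max_asa_table = sacon::max_asa_table()) {
  stopifnot(threshold_bi > 0, threshold_bi < threshold_ie, threshold_ie < 1,
            all(max_asa_table > 0))
  structure(list(threshold_bi = threshold_bi, threshold_ie = threshold_ie,
                 max_asa_table = max_asa_table),
            class = "solvent_config")
}

#' Euclidean distance between two 3D points
#'
#' @param a,b numeric length-3 coordinate vectors in Angstroms.
#' @return Non-negative distance in Angstroms.
#' @export
pairwise_distance <- function(a, b) {
  stopifnot(length(a) == 3, length(b) == 3, all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}

#' Per-residue contact-number profile
#'
#' Counts, for every residue with a resolvable contact atom, the number of
#' other residues whose contact atom lies strictly inside a sphere of radius
#' `cutoff_radius`, excluding near-sequence neighbours (`|j - i| > 2` at the
#' default separation).  Counts above `cap` collapse to `cap`, giving the
#' 15-state label at the defaults.  Residues flagged missing are excluded
#' from both the centre and neighbour roles and their labels are `NA`.
#'
#' @param coords `residue_coordinates` object (see
#'   [read_pdb_coordinates()] or [generate_structure()]).
#' @param config a [contact_config()].
#' @return A `label_track` with `task = "cn15"`, integer `labels` in
#'   `0..cap` (NA where missing), and uncapped raw counts in `real_values`.
#' @export
contact_number_profile <- function(coords, config = contact_config()) {
  stopifnot(inherits(coords, "residue_coordinates"))
  pos <- coords$positions
  miss <- coords$missing_mask
  L <- nrow(pos)
  if (all(miss)) stop("all residue coordinates are missing")
  sep <- config$sequence_separation_min - 1L  # pairs with |j-i| <= sep excluded
  raw <- rep(NA_real_, L)
  ok <- which(!miss)
  d <- as.matrix(stats::dist(pos[ok, , drop = FALSE]))
  idx <- ok  # original residue indices of rows of d
  for (k in seq_along(idx)) {
    i <- idx[k]
    qual <- abs(idx - i) > sep
    raw[i] <- sum(d[k, qual] < config$cutoff_radius)
  }
  labels <- as.integer(pmin(raw, config$cap))
  label_track(task = "cn15", labels = labels, real_values = raw)
}

#' Relative solvent accessibility
#'
#' Divides each residue's absolute ASA by the maximum ASA of its residue
#' type.  Unknown residues (`X`) use the table mean.  Values above 1
#' (distorted structures) are preserved.
#'
#' @param asa `asa_track` of absolute ASA values in square Angstroms.
#' @param sequence one-letter amino-acid string of the same length.
#' @param config a [solvent_config()].
#' @return Numeric vector of RSA fractions.
#' @export
compute_rsa <- function(asa, sequence, config = solvent_config()) {
  stopifnot(inherits(asa, "asa_track"))
  res <- strsplit(sequence, "")[[1]]
  if (length(res) != length(asa$asa))
    stop("ASA track length ", length(asa$asa),
         " does not match sequence length ", length(res))
  tab <- config$max_asa_table
  unknown <- setdiff(unique(res), c(names(tab), "X"))
  if (length(unknown))
    stop("residue type(s) absent from max-ASA table: ",
         paste(unknown, collapse = ", "))
  denom <- ifelse(res == "X", mean(tab), tab[res])
  unname(asa$asa / denom)
}

#' Three-state solvent accessibility classification
#'
#' Buried / intermediate / exposed at the standard 10% and 40% RSA
#' thresholds with half-open intervals: B on `[0, threshold_bi)`, I on
#' `[threshold_bi, threshold_ie)`, E on `[threshold_ie, Inf)`.
#'
#' @param rsa numeric vector of RSA fractions (>= 0; NA propagates).
#' @param config a [solvent_config()].
#' @return A `label_track` with `task = "sa3"`, labels in `{B, I, E}` and
#'   the RSA fractions retained in `real_values`.
#' @export
classify_rsa_three_state <- function(rsa, config = solvent_config()) {
  stopifnot(all(rsa >= 0, na.rm = TRUE))
  lab <- ifelse(rsa < config$threshold_bi, "B",
                ifelse(rsa < config$threshold_ie, "I", "E"))
  label_track(task = "sa3", labels = lab, real_values = rsa)
}

#' Per-residue label track
#'
#' @param task `"cn15"` (integer labels 0..cap) or `"sa3"` (labels B/I/E).
#' @param labels per-residue labels; NA marks residues excluded upstream.
#' @param real_values optional raw contact counts or RSA fractions.
#' @return Object of class `label_track`.
#' @export
label_track <- function(task = c("cn15", "sa3"), labels, real_values = NULL) {
  task <- match.arg(task)
  if (task == "cn15") {
    stopifnot(all(labels >= 0L, na.rm = TRUE))
  } else {
    stopifnot(all(labels %in% c("B", "I", "E") | is.na(labels)))
  }
  if (!is.null(real_values)) stopifnot(length(real_values) == length(labels))
  structure(list(task = task, labels = labels, real_values = real_values),
            class = "label_track")
}

#' @export
print.label_track <- function(x, ...) {
  cat("<label_track>", x$task, "-", length(x$labels), "residues\n")
  invisible(x)
}

#' Container for per-residue contact-atom coordinates
#'
#' @param positions L x 3 numeric matrix of coordinates in Angstroms; rows
#'   for missing residues may be NA.
#' @param missing_mask logical vector, TRUE where neither CB nor CA was
#'   resolvable.
#' @return Object of class `residue_coordinates`.
#' @export
residue_coordinates <- function(positions, missing_mask = rep(FALSE, nrow(positions))) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, length(missing_mask) == nrow(positions))
  if (any(!is.finite(positions[!missing_mask, ])))
    stop("non-finite coordinates at non-missing residues")
  structure(list(positions = positions, missing_mask = missing_mask),
            class = "residue_coordinates")
}
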