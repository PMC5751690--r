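test_that("pairwise distance is Euclidean, symmetric and non-negative", {
  expect_equal(pairwise_distance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(pairwise_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(7)
  for (k in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    expect_identical(pairwise_distance(a, b), pairwise_distance(b, a))
    expect_gte(pairwise_distance(a, b), 0)
  }
})

test_that("contact profile honours the sequence-separation filter and cap", {
  # any 3-residue chain: every pair has |j - i| <= 2, so all counts are 0
  co <- residue_coordinates(matrix(rnorm(9), 3, 3))
  expect_equal(contact_number_profile(co)$labels, c(0L, 0L, 0L))

  # 6 co-located residues: qualifying pairs give counts [3,2,1,1,2,3]
  co6 <- residue_coordinates(matrix(rnorm(18, sd = 0.1), 6, 3))
  expect_equal(contact_number_profile(co6)$real_values, c(3, 2, 1, 1, 2, 3))

  # 20 co-located residues: residue 1 sees 17 partners, capped at 14
  co20 <- residue_coordinates(matrix(rnorm(60, sd = 0.1), 20, 3))
  prof <- contact_number_profile(co20)
  expect_equal(prof$real_values[1], 17)
  expect_equal(prof$labels[1], 14L)
})

test_that("contact profile matches the brute-force O(L^2) oracle", {
  set.seed(101)
  for (rep in 1:25) {
    L <- sample(4:50, 1)
    pos <- matrix(rnorm(3 * L, sd = 4), L, 3)
    oracle <- brute_force_contacts(pos)
    got <- contact_number_profile(residue_coordinates(pos))
    expect_equal(got$real_values, oracle$raw)
    expect_equal(got$labels, as.integer(oracle$labels))
  }
})

test_that("contact counts are symmetric-pair consistent and rigid-motion invariant", {
  set.seed(55)
  pos <- matrix(rnorm(90, sd = 3), 30, 3)
  raw <- contact_number_profile(residue_coordinates(pos))$real_values
  # each qualifying contact is counted once from each side
  n_pairs <- 0
  for (i in 1:29) for (j in (i + 1):30)
    if (j - i > 2 && sqrt(sum((pos[i, ] - pos[j, ]) ^ 2)) < 7.5)
      n_pairs <- n_pairs + 1
  expect_equal(sum(raw), 2 * n_pairs)

  # rigid rotation + translation leaves the profile unchanged
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- pos %*% R + matrix(c(5, -3, 11), 30, 3, byrow = TRUE)
  raw2 <- contact_number_profile(residue_coordinates(moved))$real_values
  expect_equal(raw2, raw, tolerance = 1e-9)
})

test_that("missing-coordinate residues are excluded from both roles", {
  set.seed(3)
  pos <- matrix(rnorm(18, sd = 0.1), 6, 3)
  miss <- c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  pos[4, ] <- NA
  prof <- contact_number_profile(residue_coordinates(pos, miss))
  expect_true(is.na(prof$labels[4]))
  # with residue 4 gone, residue 1 loses one partner: pairs (1,5),(1,6)
  expect_equal(prof$real_values[1], 2)
  expect_error(
    contact_number_profile(residue_coordinates(matrix(NA_real_, 3, 3),
                                               rep(TRUE, 3))),
    "all residue coordinates are missing")
})

test_that("exactly 15 contact classes are reachable from raw counts 0..30", {
  co <- contact_config()
  labels <- pmin(0:30, co$cap)
  expect_equal(length(unique(labels)), 15)
  expect_equal(sort(unique(labels)), 0:14)
})

test_that("RSA is ASA over max-ASA with the X-mean convention", {
  cfg <- solvent_config()
  expect_equal(compute_rsa(asa_track(0), "A", cfg), 0)
  expect_equal(compute_rsa(asa_track(106), "A", cfg), 1)     # table max for ALA
  expect_equal(compute_rsa(asa_track(21.25), "A", cfg), 21.25 / 106)
  # unknown residue uses the table mean
  expect_equal(compute_rsa(asa_track(10), "X", cfg),
               10 / mean(max_asa_table()))
  expect_error(compute_rsa(asa_track(c(1, 2)), "A", cfg), "length")
})

test_that("three-state classification uses half-open 10%/40% intervals", {
  cfg <- solvent_config()
  expect_equal(classify_rsa_three_state(0, cfg)$labels, "B")
  expect_equal(classify_rsa_three_state(0.20, cfg)$labels, "I")
  expect_equal(classify_rsa_three_state(0.10, cfg)$labels, "I")  # boundary
  expect_equal(classify_rsa_three_state(0.40, cfg)$labels, "E")  # boundary
  expect_equal(classify_rsa_three_state(1.7, cfg)$labels, "E")
})

test_that("raising the I/E threshold never moves residues toward E", {
  set.seed(12)
  rsa <- runif(200, 0, 1.2)
  rank_of <- function(l) match(l, c("B", "I", "E"))
  lo <- rank_of(classify_rsa_three_state(rsa, solvent_config(0.1, 0.4))$labels)
  hi <- rank_of(classify_rsa_three_state(rsa, solvent_config(0.1, 0.6))$labels)
  expect_true(all(hi <= lo))
})
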