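test_that("weights are 1 unweighted and 1/x from the denominator set when weighted", {
  hits <- data.frame(species = rep("AAAA", 4), reference = "r",
                     position = 0:3, strand = "sense")
  expect_identical(weight_hits(hits, "unweighted")$weight, rep(1, 4))
  w <- weight_hits(hits, "weighted", denominator_x = c(AAAA = 4))
  expect_identical(w$weight, rep(0.25, 4))
  # x = 1: weighted == unweighted
  h1 <- hits[1, ]
  expect_identical(weight_hits(h1, "weighted", c(AAAA = 1))$weight, 1)
  # unmapped in denominator universe is an error
  expect_error(weight_hits(hits, "weighted", c(AAAA = 0)), "unmapped")
  expect_error(weight_hits(hits, "weighted", c(CCCC = 3)), "unmapped")
})

test_that("denominator-set choice reproduces the genome- vs dataset-weighted contrast", {
  # species with 10 genome locations, 2 of them inside the population
  pop_hits <- data.frame(species = "ACGTACGTACGTACGTACGTA",
                         reference = c("el1", "el2"), position = 5L,
                         strand = "sense")
  sp <- data.frame(sequence = "ACGTACGTACGTACGTACGTA", length = 21L,
                   expression = 1L)
  genome_w <- weight_hits(pop_hits, "weighted",
                          c(ACGTACGTACGTACGTACGTA = 10))
  dataset_w <- weight_hits(pop_hits, "weighted",
                           c(ACGTACGTACGTACGTACGTA = 2))
  expect_equal(sum(genome_w$weight), 0.2)
  expect_equal(sum(dataset_w$weight), 1.0)
})

test_that("locus metrics divide by locus length and honour full-span containment", {
  sp <- data.frame(sequence = sprintf("SP%d", 1:5), length = 21L,
                   expression = c(10L, 10L, 10L, 10L, 10L))
  # fake 21-nt species sequences
  set.seed(51)
  sp$sequence <- vapply(1:5, function(i) random_dna(21), character(1))
  hits <- data.frame(species = sp$sequence, reference = "chr",
                     position = c(0L, 100L, 200L, 300L, 400L),
                     strand = "sense")
  hw <- weight_hits(hits, "unweighted")
  m <- locus_metrics(hw, sp, list(reference = "chr", start = 0L, end = 1000L))
  expect_identical(m$species_count, 5L)
  expect_equal(m$species_per_nt, 0.005)
  expect_equal(m$expression_per_nt, 0.05)

  # no hits -> all zero
  m0 <- locus_metrics(hw, sp, list(reference = "other", start = 0L,
                                   end = 500L))
  expect_identical(m0$species_count, 0L)
  expect_equal(m0$species_per_nt, 0)
  expect_equal(m0$expression_per_nt, 0)

  expect_error(locus_metrics(hw, sp, list(reference = "chr", start = 5L,
                                          end = 5L)), "zero-length")

  # a hit whose span crosses the locus end is excluded
  hits2 <- data.frame(species = sp$sequence[1], reference = "chr",
                      position = 990L, strand = "sense")
  m2 <- locus_metrics(weight_hits(hits2, "unweighted"), sp,
                      list(reference = "chr", start = 0L, end = 1000L))
  expect_identical(m2$species_count, 0L)
})

test_that("weighted species density equals the hand-summed 1/x tally", {
  # 5 species, known x and in-locus hit counts
  sp <- data.frame(
    sequence = c("A1", "A2", "A3", "A4", "A5"),
    length = 2L, expression = c(1L, 2L, 3L, 4L, 5L))
  x <- c(A1 = 1, A2 = 2, A3 = 4, A4 = 5, A5 = 10)
  hits <- data.frame(
    species = c("A1", "A2", "A2", "A3", "A4", "A4", "A5"),
    reference = "chr",
    position = c(10L, 20L, 30L, 40L, 50L, 60L, 70L),
    strand = "sense")
  hw <- weight_hits(hits, "weighted", x)
  m <- locus_metrics(hw, sp, list(reference = "chr", start = 0L, end = 100L),
                     scheme = "weighted")
  by_hand <- (1 / 1 + 2 * (1 / 2) + 1 / 4 + 2 * (1 / 5) + 1 / 10) / 100
  expect_equal(m$species_per_nt, by_hand)
  by_hand_expr <- (1 * 1 + 2 * 0.5 * 2 + 3 * 0.25 + 4 * 0.2 * 2 + 5 * 0.1) / 100
  expect_equal(m$expression_per_nt, by_hand_expr)
})

test_that("window profiles assign hits by 5'-most in-locus coordinate", {
  sp <- data.frame(sequence = "ACGTACGTACGTACGTACGTA", length = 21L,
                   expression = 7L)
  locus <- list(reference = "chr", start = 0L, end = 200L)
  hits <- data.frame(species = sp$sequence, reference = "chr",
                     position = 10L, strand = "sense")
  pr <- window_profile(weight_hits(hits, "unweighted"), sp, locus,
                       n_windows = 100)
  expect_true(all(pr$win_length == 2L))
  s <- pr[pr$strand == "sense", ]
  expect_identical(which(s$species_density > 0), 6L)  # window 5 0-based
  expect_true(all(pr$species_density[pr$strand == "antisense"] == 0))

  # antisense 5' end is the rightmost base
  hits_a <- data.frame(species = sp$sequence, reference = "chr",
                       position = 10L, strand = "antisense")
  pra <- window_profile(weight_hits(hits_a, "unweighted"), sp, locus, 100)
  a <- pra[pra$strand == "antisense", ]
  expect_identical(which(a$species_density > 0), 16L)  # floor(30/2) 0-based

  expect_error(window_profile(weight_hits(hits, "unweighted"), sp,
                              list(reference = "chr", start = 0L, end = 50L),
                              100), "n_windows")
})

test_that("window densities conserve locus totals for both metrics and schemes", {
  b <- small_bundle(52)
  el <- b$sg$truth$elements
  gidx <- build_index(b$sg$genome, c(21, 22, 24), "genome")
  hits <- map_species_table(b$library$species, gidx)
  xg <- species_locations(hits, b$library$species)
  locus <- list(reference = el$reference_id[1], start = el$start[1],
                end = el$end[1])
  for (scheme in c("unweighted", "weighted")) {
    hw <- if (scheme == "unweighted") weight_hits(hits, "unweighted")
          else weight_hits(hits, "weighted", xg)
    pr <- window_profile(hw, b$library$species, locus, 100)
    # independent locus totals: direct sums over fully-contained hits
    len <- nchar(hw$species)
    inl <- hw$reference == locus$reference & hw$position >= locus$start &
      hw$position + len <= locus$end
    expr <- b$library$species$expression[
      match(hw$species[inl], b$library$species$sequence)]
    expect_equal(sum(pr$species_density * pr$win_length),
                 sum(hw$weight[inl]), tolerance = 1e-12)
    expect_equal(sum(pr$expression_density * pr$win_length),
                 sum(expr * hw$weight[inl]), tolerance = 1e-12)
    expect_true(sum(pr$species_density) > 0)
  }
})

test_that("weight conservation: each mapped species contributes exactly 1 genome-wide", {
  b <- small_bundle(53)
  gidx <- build_index(b$sg$genome, c(21, 22, 24), "genome")
  hits <- map_species_table(b$library$species, gidx)
  xg <- species_locations(hits, b$library$species)
  hw <- weight_hits(hits, "weighted", xg)
  per_species <- tapply(hw$weight, hw$species, sum)
  expect_true(all(abs(per_species - 1) < 1e-9))
  expect_equal(sum(hw$weight), sum(xg$x > 0), tolerance = 1e-9)
})

test_that("metric consistency: species metric ignores expression, expression scales linearly", {
  b <- small_bundle(54)
  pidx <- build_index(b$population, c(21, 22, 24), "population")
  hits <- map_species_table(b$library$species, pidx)
  hw <- weight_hits(hits, "unweighted")
  rl <- stats::setNames(nchar(b$population), names(b$population))
  d1 <- density_per_reference(hw, b$library$species, rl)
  sp2 <- b$library$species
  sp2$expression <- sp2$expression * 3L
  d2 <- density_per_reference(hw, sp2, rl)
  expect_equal(d1$species_per_nt, d2$species_per_nt)
  expect_equal(d2$expression_per_nt, 3 * d1$expression_per_nt)

  # unweighted tallies dominate weighted ones everywhere
  xp <- species_locations(hits, b$library$species)
  hww <- weight_hits(hits, "weighted", xp)
  dw <- density_per_reference(hww, b$library$species, rl,
                              scheme = "dataset-weighted")
  expect_true(all(dw$species_per_nt <= d1$species_per_nt + 1e-12))
  expect_true(all(dw$expression_per_nt <= d1$expression_per_nt + 1e-12))
})

test_that("U:M proportions are over mapped species only", {
  r <- um_ratio(c(1L, 1L, rep(5L, 8)))
  expect_equal(r$prop_U, 0.2)
  expect_equal(r$prop_M, 0.8)
  expect_equal(um_ratio(rep(1L, 4))$prop_U, 1)
  r0 <- um_ratio(c(0L, 0L))
  expect_true(is.na(r0$prop_U) && is.na(r0$prop_M))
})
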