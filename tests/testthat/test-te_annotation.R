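test_that("length peaks are local maxima of the binned distribution", {
  lengths <- c(rep(100, 10), rep(200, 50), rep(300, 12))
  # every isolated occupied bin is a local maximum...
  expect_identical(nrow(length_peaks(lengths, bin_width = 10)), 3L)
  # ...and min_prominence singles out the dominant full-length mode
  pk <- length_peaks(lengths, bin_width = 10, min_prominence = 12)
  expect_identical(nrow(pk), 1L)
  expect_true(pk$low <= 200 && 200 <= pk$high)
  expect_identical(pk$count, 50L)

  # uniform lengths: the single occupied bin is the peak
  pk1 <- length_peaks(rep(5000, 20), bin_width = 100)
  expect_identical(nrow(pk1), 1L)

  # bimodal mixture (7.3 kb and 9.4 kb modes) recovers two peaks
  set.seed(61)
  mix <- c(round(rnorm(300, 7300, 120)), round(rnorm(200, 9400, 120)),
           round(runif(80, 2000, 12000)))
  pk2 <- length_peaks(mix, bin_width = 200, min_prominence = 10)
  expect_identical(nrow(pk2), 2L)
  expect_true(any(abs(pk2$mode - 7300) < 400))
  expect_true(any(abs(pk2$mode - 9400) < 400))
})

test_that("full-length candidate selection is an inclusive length filter", {
  set.seed(62)
  lens <- c(round(runif(63, 2000, 12000)), round(runif(37, 13300, 14100)))
  keep <- select_fulllength_candidates(lens, c(13300, 14100))
  expect_identical(sum(keep), 37L)
  expect_identical(sum(select_fulllength_candidates(lens, c(20000, 30000))),
                   0L)
  expect_true(all(select_fulllength_candidates(lens, c(1, 1e6))))
})

test_that("LTR pair alignment matches the exhaustive-enumeration oracle", {
  a <- align_ltr_pair("ACGT", "ACGT")
  expect_identical(a$aligned_a, a$aligned_b)
  expect_identical(a$score, 4)

  a2 <- align_ltr_pair("ACGT", "ACT")
  expect_identical(a2$score, -2)            # 3 matches, one 1-nt gap
  expect_identical(nchar(a2$aligned_a), 4L)
  expect_identical(sum(strsplit(a2$aligned_b, "")[[1]] == "-"), 1L)

  set.seed(63)
  for (i in 1:12) {
    la <- sample(2:6, 1); lb <- sample(2:6, 1)
    s1 <- random_dna(la); s2 <- random_dna(lb)
    expect_identical(align_ltr_pair(s1, s2)$score,
                     oracle_align_score(s1, s2),
                     info = paste(s1, s2))
  }
  s1 <- random_dna(8); s2 <- random_dna(8)
  expect_identical(align_ltr_pair(s1, s2)$score, oracle_align_score(s1, s2))
})

test_that("divergence closed forms match hand arithmetic and ape", {
  id <- list(aligned_a = strrep("ACGT", 25), aligned_b = strrep("ACGT", 25))
  for (m in c("p", "JC69", "K2P")) {
    expect_equal(ltr_divergence(id, m)$K, 0)
  }

  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("G", 5), strrep("C", 5), strrep("A", 90))   # p = 0.1
  expect_equal(ltr_divergence(list(aligned_a = s1, aligned_b = s2),
                              "JC69")$K, -0.75 * log(1 - 0.4 / 3),
               tolerance = 1e-12)
  expect_equal(ltr_divergence(list(aligned_a = s1, aligned_b = s2),
                              "JC69")$K, 0.10732, tolerance = 1e-4)

  s3 <- paste0(strrep("G", 6), strrep("C", 4), strrep("A", 90))  # P=.06 Q=.04
  k2p <- ltr_divergence(list(aligned_a = s1, aligned_b = s3), "K2P")
  expect_identical(k2p$transitions, 6L)
  expect_identical(k2p$transversions, 4L)
  expect_equal(round(k2p$K, 5), 0.10802)

  # gap and N columns are excluded from n
  g <- ltr_divergence(list(aligned_a = "AC-GTN", aligned_b = "ACTGAA"), "p")
  expect_identical(g$n_sites, 4L)
  expect_equal(g$p_distance, 0.25)

  # saturation is explicit, not clamped
  sat <- ltr_divergence(list(aligned_a = strrep("A", 100),
                             aligned_b = strrep("G", 100)), "JC69")
  expect_true(is.na(sat$K) && sat$saturated)

  # cross-check against ape::dist.dna on random diverged pairs
  skip_if_not_installed("ape")
  set.seed(64)
  for (i in 1:5) {
    s <- random_dna(400)
    chars <- strsplit(s, "")[[1]]
    mut <- sample(400, 30)
    chars2 <- chars
    chars2[mut] <- vapply(chars[mut], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    m <- matrix(c(chars, chars2), nrow = 2, byrow = TRUE)
    bin <- ape::as.DNAbin(tolower(m))
    ours <- ltr_divergence(list(aligned_a = s,
                                aligned_b = paste(chars2, collapse = "")))
    expect_equal(ours$K, as.numeric(ape::dist.dna(bin, model = "K80")),
                 tolerance = 1e-9)
    oj <- ltr_divergence(list(aligned_a = s,
                              aligned_b = paste(chars2, collapse = "")),
                         "JC69")
    expect_equal(oj$K, as.numeric(ape::dist.dna(bin, model = "JC69")),
                 tolerance = 1e-9)
  }
})

test_that("K is monotone in p and bounded below by p", {
  ps <- seq(0, 0.45, by = 0.05)
  mk <- function(p) {
    n <- 200
    d <- round(p * n)
    list(aligned_a = strrep("A", n),
         aligned_b = paste0(strrep("G", d), strrep("A", n - d)))
  }
  for (m in c("JC69", "K2P")) {
    Ks <- vapply(ps, function(p) ltr_divergence(mk(p), m)$K, numeric(1))
    expect_true(all(diff(Ks) >= 0))
    expect_true(all(Ks >= ps - 1e-12))
  }
})

test_that("ages follow T = K/(2r) and the clock recovers simulated ages", {
  expect_identical(estimate_age(0), 0)
  expect_equal(estimate_age(0.0026, 1.3e-8), 1e5)
  expect_error(estimate_age(0.1, 0), "positive")
  expect_equal(estimate_age(c(0.01, 0.02)), 2 * estimate_age(c(0.005, 0.01)))
  expect_equal(estimate_age(0.01, 2.6e-8), estimate_age(0.01, 1.3e-8) / 2)

  # end-to-end recovery through annotations and the aligner
  fs <- family_spec("fam", 60, ltr_length = 1000, int_length = 100,
                    hotspot = c(10, 20), age_params = c(1e6, 1e6),
                    hotspot_factor = 1)
  sg <- assemble_genome(list(simulate_family(fs, 65)),
                        background_length = 40000, seed = 66)
  ages <- ages_from_annotations(sg$genome, sg$annotations, model = "JC69")
  expect_identical(nrow(ages), 60L)
  expect_lt(median(abs(ages$age_years - 1e6)) / 1e6, 0.15)
})

test_that("contamination screen reports planted fragments and respects thresholds", {
  set.seed(67)
  host <- random_dna(2000)
  donor <- random_dna(1500)
  frag <- substring(donor, 301, 489)  # 189 nt
  host2 <- paste0(substring(host, 1, 800), frag, substring(host, 990, 2000))
  cs <- contamination_screen(c(h1 = host2), c(d1 = donor),
                             donor_families = "famX")
  expect_identical(nrow(cs), 1L)
  expect_gte(cs$length, 189L)
  expect_true(cs$host_start <= 800 && cs$host_end >= 989)
  expect_gte(cs$identity, 0.99)

  # reverse-complemented fragments are found too
  host3 <- paste0(substring(host, 1, 800), revcomp(frag),
                  substring(host, 990, 2000))
  cs3 <- contamination_screen(c(h1 = host3), c(d1 = donor),
                              donor_families = "famX")
  expect_identical(nrow(cs3), 1L)
  expect_gte(cs3$length, 189L)

  # no shared seed -> no hit
  cs0 <- contamination_screen(c(h1 = random_dna(600)),
                              c(d1 = strrep("AC", 300)),
                              donor_families = "famY")
  expect_identical(nrow(cs0), 0L)

  # planted 50 nt fragment below min_match is not reported
  host4 <- paste0(substring(host, 1, 200), substring(donor, 1, 50),
                  substring(host, 251, 900))
  cs4 <- contamination_screen(c(h1 = host4), c(d1 = donor),
                              donor_families = "famX")
  expect_identical(nrow(cs4), 0L)
})

test_that("BLAST tabular import filters at the E-value cutoff", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "donor1\thostA\t98.5\t210\t3\t0\t1\t210\t501\t710\t1e-50\t380",
    "donor2\thostA\t91.0\t120\t10\t1\t1\t118\t901\t1020\t1e-10\t90"
  ), p)
  h <- import_blast_hits(p)
  expect_identical(nrow(h), 1L)
  expect_identical(h$host_start, 500L)
  expect_identical(h$host_end, 710L)
  expect_equal(h$identity, 0.985)
})
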