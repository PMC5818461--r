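test_that("an exact planted copy is found with full coverage and identity", {
  tmpl <- fix_templates(2)
  ref <- paste0(tmpl$A$ltr_seq, tmpl$A$internal_seq, tmpl$A$ltr_seq)
  g <- paste0(make_background(20000, 0.38, 1), ref,
              make_background(20000, 0.38, 2))
  hits <- census_scan(ref, g, family = "A")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 20000)
  expect_equal(hits$end, 20000 + nchar(ref))
  expect_equal(hits$identity, 1)
  expect_equal(hits$coverage, 1)
  expect_identical(hits$strand, "+")
})

test_that("a truncated diverged copy reports the planted coverage and identity", {
  tmpl <- fix_templates(2)
  ref <- paste0(tmpl$A$ltr_seq, tmpl$A$internal_seq, tmpl$A$ltr_seq)
  half <- substr(ref, 1, nchar(ref) %/% 2)
  div <- substitute_k(half, round(0.1 * nchar(half)), seed = 5)
  g <- paste0(make_background(15000, 0.38, 3), div,
              make_background(15000, 0.38, 4))
  hits <- census_scan(ref, g, family = "A")
  expect_equal(nrow(hits), 1)
  expect_lt(abs(hits$coverage - 0.5), 0.02)
  expect_lt(abs(hits$identity - 0.9), 0.02)
})

test_that("reverse-strand copies are found with the correct strand", {
  tmpl <- fix_templates(2)
  ref <- paste0(tmpl$A$ltr_seq, tmpl$A$internal_seq, tmpl$A$ltr_seq)
  g <- paste0(make_background(15000, 0.38, 6), revcomp(ref),
              make_background(15000, 0.38, 7))
  hits <- census_scan(ref, g, family = "A")
  expect_equal(nrow(hits), 1)
  expect_identical(hits$strand, "-")
  expect_equal(hits$start, 15000)
})

test_that("genomes without planted copies give an empty census", {
  tmpl <- fix_templates(2)
  ref <- paste0(tmpl$A$ltr_seq, tmpl$A$internal_seq, tmpl$A$ltr_seq)
  for (seed in 1:3) {
    g <- make_background(60000, 0.38, seed + 30)
    expect_equal(nrow(census_scan(ref, g)), 0)
  }
})

test_that("copy calling applies the strict 80-80 / 80-10 thresholds", {
  mk <- function(cov, idv) data.frame(family = "A", start = 0, end = 100,
                                      strand = "+", identity = idv,
                                      coverage = cov)
  cc <- call_copies(mk(0.85, 0.90))
  expect_identical(cc$completeness, "complete")
  cc <- call_copies(mk(0.50, 0.85))
  expect_identical(cc$completeness, "fragment")
  expect_equal(nrow(call_copies(mk(0.85, 0.80))), 0)   # strict >
  expect_equal(nrow(call_copies(mk(0.80, 0.95))), 1)   # 0.80 coverage: fragment
  expect_identical(call_copies(mk(0.80, 0.95))$completeness, "fragment")
  expect_equal(nrow(call_copies(mk(0.10, 0.95))), 0)
  # classes are disjoint on a grid
  grid <- expand.grid(cov = seq(0.05, 1, by = 0.05),
                      idv = seq(0.05, 1, by = 0.05))
  hits <- data.frame(family = "A", start = 0, end = 100, strand = "+",
                     identity = grid$idv, coverage = grid$cov)
  out <- call_copies(hits)
  expect_equal(sum(out$completeness == "complete") +
                 sum(out$completeness == "fragment"), nrow(out))
})

test_that("K2P distance matches the closed form and flags saturation", {
  a <- paste(rep("A", 700), collapse = "")
  kd <- k2p_distance(a, a)
  expect_equal(c(kd$P, kd$Q, kd$K), c(0, 0, 0))
  # 7 transitions among 700 ungapped columns
  b <- substitute_k(rand_nt(700, seed = 1), 0)
  b2 <- substitute_k(b, 7, seed = 2, transitions_only = TRUE)
  kd <- k2p_distance(b, b2)
  expect_equal(kd$P, 0.01)
  expect_equal(kd$Q, 0)
  expect_equal(kd$K, -0.5 * log(0.98), tolerance = 1e-12)
  # symmetry
  kd2 <- k2p_distance(b2, b)
  expect_equal(kd$K, kd2$K)
  # saturation boundary: P=0.4, Q=0.2 makes 1-2P-Q = 0
  x <- strsplit(paste(rep("A", 10), collapse = ""), "")[[1]]
  y <- c(rep("G", 4), rep("C", 2), rep("A", 4))
  kd3 <- k2p_distance(paste(x, collapse = ""), paste(y, collapse = ""),
                      already_aligned = TRUE)
  expect_true(kd3$saturated)
  expect_true(is.na(kd3$K))
})

test_that("insertion time is exact arithmetic, linear in K and 1/r", {
  expect_equal(insertion_time(0), 0)
  expect_equal(insertion_time(0.026, 1.3e-8), 1e6)
  for (K in c(0.01, 0.05, 0.2)) {
    expect_equal(insertion_time(2 * K), 2 * insertion_time(K))
    expect_equal(insertion_time(K, 2.6e-8), insertion_time(K, 1.3e-8) / 2)
  }
  expect_error(insertion_time(0.1, 0), "positive")
  expect_error(insertion_time(-0.1), "non-negative")
})

test_that("density tracks cover windows correctly and flatten overlaps", {
  ann <- data.frame(start = 20000, end = 30000)
  tr <- density_profile(ann, 100000, 10000, 10000)
  expect_equal(nrow(tr), 10)
  expect_equal(tr$value[tr$start == 20000], 1)
  expect_equal(sum(tr$value), 1)
  # two abutting annotations behave as their union
  ab <- data.frame(start = c(20000, 25000), end = c(25000, 30000))
  tr2 <- density_profile(ab, 100000, 10000, 10000)
  expect_equal(tr2$value, tr$value)
  cnt <- density_profile(ann, 100000, 10000, 10000, mode = "count")
  expect_equal(sum(cnt$value), 1)
  expect_warning(density_profile(ann, 50000, 80000, 1000), "single")
})

test_that("a centrally clustered planting shows the expected density contrast", {
  set.seed(3)
  centre <- data.frame(start = sort(sample(40000:59000, 16)), end = 0)
  centre$end <- centre$start + 500
  flank <- data.frame(start = sort(sample(c(0:30000, 70000:99000), 4)), end = 0)
  flank$end <- flank$start + 500
  tr <- density_profile(rbind(centre, flank), 100000, 10000, 10000)
  mid <- tr$value[tr$start >= 40000 & tr$start < 60000]
  outer <- tr$value[tr$start < 30000 | tr$start >= 70000]
  expect_gt(mean(mid), 3 * mean(outer))
})

test_that("tandem arrays are found with the right period and CRC-only regions
           stay silent", {
  bg <- make_background(80000, 0.38, 3)
  mono <- make_background(170, 0.45, 8)
  arr <- plant_tandem_array(bg, mono, 50, 10000, 0.02, 5)
  ta <- detect_tandem_arrays(arr$genome, 50, 1000, 5)
  expect_equal(nrow(ta), 1)
  expect_lte(abs(ta$period - 170), 2)
  expect_lt(abs(ta$copies - 50), 3)
  expect_lte(abs(ta$start - 10000), 170)
  # zero divergence: all copies identical
  arr0 <- plant_tandem_array(bg, mono, 20, 10000, 0, 5)
  ta0 <- detect_tandem_arrays(arr0$genome, 50, 1000, 5)
  expect_equal(nrow(ta0), 1)
  expect_equal(ta0$monomer_identity, 100)
  # random backgrounds and element-only genomes are negative
  expect_equal(nrow(detect_tandem_arrays(bg, 50, 1000, 5)), 0)
  sim <- fix_small_sim()
  expect_equal(nrow(detect_tandem_arrays(sim$genome, 50, 1000, 5)), 0)
  expect_error(detect_tandem_arrays(bg, 1, 100, 5), "min_period")
})

test_that("region composition reports flattened per-category percentages", {
  ann <- data.frame(category = c("TE", "TE", "CRC"),
                    start = c(0, 500, 200), end = c(600, 1000, 400))
  comp <- region_composition(ann, c(0, 1000))
  expect_equal(comp$percent[comp$category == "TE"], 100)
  expect_equal(comp$percent[comp$category == "CRC"], 20)
  expect_error(region_composition(data.frame(category = "TE", start = -5,
                                             end = 10), c(0, 1000)),
               "outside")
  # constructed composition matches planted fractions
  set.seed(9)
  reg <- c(0, 800000)
  te_starts <- seq(0, 799000, by = 1000)
  te <- data.frame(category = "TE", start = te_starts, end = te_starts + 900)
  crc <- data.frame(category = "CRC", start = te_starts[seq(1, 800, by = 3)],
                    end = te_starts[seq(1, 800, by = 3)] + 900)
  comp2 <- region_composition(rbind(te, crc), reg)
  expect_lt(abs(comp2$percent[comp2$category == "TE"] - 90), 1)
  expect_lt(abs(comp2$percent[comp2$category == "CRC"] - 30), 1.5)
})

test_that("age histograms expose planted accumulation peaks", {
  set.seed(12)
  tri <- c(rnorm(60, 0.5e6, 0.5e5), rnorm(60, 1.5e6, 0.5e5),
           rnorm(60, 3e6, 0.5e5))
  h <- age_histogram(tri, bin_width_years = 1e5)
  expect_length(h$peaks, 3)
  expect_lt(abs(h$peaks[1] - 0.5e6), 1e5)
  expect_lt(abs(h$peaks[2] - 1.5e6), 1e5)
  expect_lt(abs(h$peaks[3] - 3e6), 1e5)
  one <- age_histogram(rnorm(80, 0.5e6, 0.5e5), bin_width_years = 1e5)
  expect_length(one$peaks, 1)
  empty <- age_histogram(numeric(0), 1e5)
  expect_length(empty$peaks, 0)
})

test_that("the planted copy table is reproduced exactly in the noiseless case", {
  tmpl <- fix_templates(3)
  bg <- make_background(120000, 0.38, 21)
  ev <- data.frame(template = c("A", "B", "A", "C"),
                   locus = c(15000, 45000, 75000, 105000),
                   age_years = 0, decay = "complete")
  pl <- plant_elements(bg, tmpl, ev, seed = 14)
  idx <- crckit:::kmer_table(pl$genome, census_config()$seed_kmer)
  counts <- vapply(names(tmpl), function(f) {
    ref <- paste0(tmpl[[f]]$ltr_seq, tmpl[[f]]$internal_seq, tmpl[[f]]$ltr_seq)
    hits <- census_scan(ref, pl$genome, family = f, genome_index = idx)
    sum(call_copies(hits)$completeness == "complete")
  }, numeric(1))
  expect_equal(unname(counts), c(2, 1, 1))
})
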