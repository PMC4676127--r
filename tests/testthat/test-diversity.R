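make_vs <- function(scaffold, pos, geno, depth = NULL) {
  geno <- as.matrix(geno)
  list(sites = data.frame(scaffold = rep_len(scaffold, length(pos)),
                          pos = pos, stringsAsFactors = FALSE),
       geno = geno,
       depth = if (is.null(depth)) NULL else as.matrix(depth))
}

test_that("depth filter keeps inclusive bounds and drops out-of-range sites", {
  vs <- make_vs("s", 1:3,
                geno = matrix(1, 3, 3),
                depth = rbind(c(5, 30, 12),   # boundary values kept
                              c(4, 20, 20),   # one sample below min
                              c(10, 31, 10))) # one sample above max
  out <- filter_by_depth(vs, 5, 30)
  expect_equal(out$sites$pos, 1L)
  log <- attr(out, "filter_log")
  expect_equal(log$n_kept, 1)
  expect_equal(log$n_dropped_range, 2)
})

test_that("depth filter equals a per-site brute-force check on random input", {
  set.seed(11)
  n <- 100
  depth <- matrix(sample(1:40, n * 4, replace = TRUE), n, 4)
  vs <- make_vs("s", seq_len(n), matrix(1, n, 4), depth)
  out <- filter_by_depth(vs, 5, 30)
  brute <- which(apply(depth, 1, function(d) all(d >= 5 & d <= 30)))
  expect_equal(out$sites$pos, brute)
  # widening the bounds never decreases the kept count
  wider <- filter_by_depth(vs, 3, 35)
  expect_gte(nrow(wider$sites), nrow(out$sites))
})

test_that("sites with missing depth are dropped and logged", {
  d <- matrix(10, 3, 2); d[2, 1] <- NA
  vs <- make_vs("s", 1:3, matrix(1, 3, 2), d)
  out <- filter_by_depth(vs)
  expect_equal(attr(out, "filter_log")$n_dropped_missing, 1)
  expect_equal(out$sites$pos, c(1L, 3L))
})

test_that("mask filter uses the VCF-point-in-BED-interval rule", {
  vs <- make_vs("s", c(10, 11, 20, 21), matrix(1, 4, 1))
  mask <- data.frame(scaffold = "s", start = 10, end = 20)  # covers pos 11..20
  res <- filter_by_mask(vs, mask)
  expect_equal(res$kept$sites$pos, c(10, 21))
  expect_equal(res$removed$sites$pos, c(11, 20))
})

test_that("mask filtering is idempotent and handles edge cases", {
  set.seed(5)
  vs <- make_vs("s", sort(sample(1:10000, 200)), matrix(1, 200, 1))
  mask <- data.frame(scaffold = "s",
                     start = c(100, 2000, 5000), end = c(600, 2500, 9000))
  once <- filter_by_mask(vs, mask)
  twice <- filter_by_mask(once$kept, mask)
  expect_equal(twice$kept$sites, once$kept$sites)
  expect_equal(filter_by_mask(vs, mask[0, ])$retention_percent, 100)
  expect_warning(filter_by_mask(vs, data.frame(scaffold = "nope",
                                               start = 1, end = 5)),
                 "nope")
})

test_that("toy mask filtering and retention match hand counts", {
  vs <- make_vs("s", c(1, 5, 10, 15, 20, 25, 30, 35, 40, 45),
                matrix(1, 10, 1))
  mask <- data.frame(scaffold = "s", start = c(4, 24), end = c(15, 40))
  res <- filter_by_mask(vs, mask)
  # masked: 5, 10, 15 (start<pos<=end), 25, 30, 35, 40 -> 7 removed? No:
  # intervals (4,15] and (24,40] -> removed 5,10,15,25,30,35,40
  expect_equal(nrow(res$removed$sites), 7)
  expect_equal(nrow(res$kept$sites), 3)
  expect_equal(retention_percent(1820419, 3438824), 53)
})

test_that("per-individual SNV rates equal a brute-force genotype scan", {
  sc <- const_scenario(L = 1e5, n = 6, n_loci = 10)
  co <- simulate_two_pop_cohort(sc, 3)
  r <- snv_rate(co, 1e5)
  brute <- apply(co$geno, 2, function(g) sum(g > 0)) / 1e5
  expect_equal(unname(r), unname(brute))
  expect_equal(unname(snv_rate(make_vs("s", integer(), matrix(0, 0, 2)),
                               1e6)), c(0, 0))
  expect_error(snv_rate(co, 0), "genome_length")
})

test_that("window density tiles scaffolds and drops short ones", {
  lens <- c(a = 49999, b = 150000, c = 125000)
  vs <- make_vs(c("b", "b", "b", "c"), c(1, 50000, 149999, 120000),
                matrix(1, 4, 1))
  wd <- window_density(vs, lens, window = 50000)
  expect_equal(sum(wd$scaffold == "a"), 0)
  expect_equal(sum(wd$scaffold == "b"), 3)
  expect_equal(sum(wd$scaffold == "c"), 2)
  expect_equal(attr(wd, "n_excluded_scaffolds"), 1)
  # pos 1 -> window 1; pos 50000 -> window 1; 149999 -> window 3
  expect_equal(wd$snv_count[wd$scaffold == "b"], c(2, 0, 1))
  # trailing 25 kb of c and site at 120000 lands in window 3 (dropped)
  expect_equal(wd$snv_count[wd$scaffold == "c"], c(0, 0))
})

test_that("window counts conserve sites and match brute-force binning", {
  set.seed(21)
  lens <- c(x = 2e5, y = 1.2e5)
  pos <- c(sort(sample(1:2e5, 300)), sort(sample(1:1.2e5, 150)))
  vs <- make_vs(rep(c("x", "y"), c(300, 150)), pos, matrix(1, 450, 1))
  wd <- window_density(vs, lens, window = 50000)
  brute <- 0
  for (nm in names(lens)) {
    p <- vs$sites$pos[vs$sites$scaffold == nm]
    nw <- lens[[nm]] %/% 50000
    brute <- brute + sum(p <= nw * 50000)
    cnt <- tabulate(pmin((p - 1) %/% 50000 + 1, nw + 1), nbins = nw + 1)[1:nw]
    expect_equal(wd$snv_count[wd$scaffold == nm],
                 tabulate((p[p <= nw * 50000] - 1) %/% 50000 + 1, nbins = nw))
  }
  expect_equal(sum(wd$snv_count), brute)
})

test_that("het/hom window classification applies a strict threshold", {
  lens <- c(s = 3e5)
  # window 1: 41 het sites -> heterozygous; window 2: 40 -> homozygous
  pos <- c(seq(1, by = 10, length.out = 41),
           seq(100001, by = 10, length.out = 40))
  vs <- make_vs("s", pos, matrix(1, length(pos), 1))
  win <- classify_het_hom(vs, 1, lens, window = 100000, threshold = 40)
  expect_equal(win$label, c("heterozygous", "homozygous", "homozygous"))
  expect_equal(attr(win, "percent_homozygous"), 100 * 2 / 3)
  # an all-homozygous individual gives 100 % homozygous windows
  vs0 <- make_vs("s", pos, matrix(2, length(pos), 1))
  win0 <- classify_het_hom(vs0, 1, lens, window = 100000)
  expect_equal(attr(win0, "percent_homozygous"), 100)
})

test_that("higher diversity lowers the homozygous-window fraction", {
  lens <- c(scf1 = 1e6)
  high <- demography_scenario("CONST", sample_sizes = 4,
                              ancestral_size = 50000, mutation_rate = 1e-8,
                              mutation_rate_units = "per_generation",
                              sequence_length = 1e6, n_loci = 1)
  low <- demography_scenario("CONST", sample_sizes = 4,
                             ancestral_size = 5000, mutation_rate = 1e-8,
                             mutation_rate_units = "per_generation",
                             sequence_length = 1e6, n_loci = 1)
  ph <- function(sc, seeds) mean(vapply(seeds, function(s) {
    co <- simulate_two_pop_cohort(sc, s)
    attr(classify_het_hom(co, 1, lens, window = 100000, threshold = 5),
         "percent_homozygous")
  }, numeric(1)))
  expect_gt(ph(low, 1:10), ph(high, 1:10))
})

test_that("heterozygosity rate matches a brute-force tally", {
  sc <- const_scenario(L = 1e5, n = 6, n_loci = 10)
  co <- simulate_two_pop_cohort(sc, 9)
  hr <- heterozygosity_rate(co, 1e6)
  expect_equal(unname(hr), unname(colSums(co$geno == 1) / 1e6 * 100))
  expect_equal(unname(heterozygosity_rate(
    make_vs("s", 1:3, matrix(c(0, 2, 0), 3, 1)), 1e6)), 0)
  expect_error(heterozygosity_rate(co, 0), "callable_length")
})

test_that("tandem repeat classes follow the stated thresholds", {
  rec <- data.frame(
    monomer_len = c(4, 6, 6, 2, 6),
    array_len = c(80, 500, 500, 12000, 90),
    copy_number = c(20, 80, 80, 6000, 15),
    gc = c(50, 50, 10, 50, 50),
    entropy = c(1.9, 1.8, 1.8, 1.9, 1.8),
    perfect = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    cn_variation_bp = c(0, 10, 10, 10, 10))
  out <- classify_tandem_repeats(rec)
  expect_true(out$microsatellite[1])
  expect_true(out$complex[2])           # all complex conditions met
  expect_false(out$complex[3])          # GC out of range
  expect_equal(out$large_class[4], "10kb")
  expect_false(out$complex[5])          # array too short
  expect_false(any(out$unclassifiable))
})

test_that("random tandem records match brute-force rule evaluation", {
  set.seed(31)
  n <- 200
  rec <- data.frame(
    monomer_len = sample(1:30, n, TRUE),
    array_len = sample(10:20000, n, TRUE),
    copy_number = sample(2:500, n, TRUE),
    gc = runif(n, 0, 100),
    entropy = runif(n, 1, 2),
    perfect = sample(c(TRUE, FALSE), n, TRUE),
    cn_variation_bp = sample(0:20, n, TRUE))
  out <- classify_tandem_repeats(rec)
  expect_equal(out$microsatellite, rec$monomer_len < 5)
  expect_equal(out$complex,
               rec$monomer_len > 4 & rec$gc >= 20 & rec$gc <= 80 &
                 rec$array_len > 100 & rec$entropy > 1.76 &
                 rec$cn_variation_bp > 4 & !rec$perfect)
  big <- rec$array_len >= 1000
  expect_true(all(is.na(out$large_class[!big])))
  expect_true(all(!is.na(out$large_class[big])))
  # a record with a missing field is unclassifiable
  rec$entropy[1] <- NA
  out2 <- classify_tandem_repeats(rec)
  expect_true(out2$unclassifiable[1])
})
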