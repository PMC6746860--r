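test_that("pooled enrichment is the ratio of summed counts", {
  ct <- counts_table(rep("g1", 1), "bc1", "blue", 100, 50)
  expect_equal(allele_enrichment(ct, n_boot = 0)$enrichment, 0.5)
  ct2 <- counts_table(rep("g1", 2), c("bc1", "bc2"), rep("blue", 2),
                      c(100, 300), c(50, 150))
  expect_equal(allele_enrichment(ct2, n_boot = 0)$enrichment, 0.5)
  # sum-of-ratios mode averages per-barcode ratios
  ct3 <- counts_table(rep("g1", 2), c("bc1", "bc2"), rep("blue", 2),
                      c(100, 100), c(50, 150))
  expect_equal(
    allele_enrichment(ct3, method = "sum_of_ratios", n_boot = 0)$enrichment,
    1)
  expect_error(
    allele_enrichment(counts_table("g1", "bc1", "blue", 0, 5), n_boot = 0),
    "all-zero input")
})

test_that("bootstrap sd brackets a known simulated enrichment", {
  set.seed(10)
  n_bc <- 20
  n_in <- rpois(n_bc, 200)
  n_out <- rpois(n_bc, 2 * n_in)  # true enrichment 2.0
  ct <- counts_table(rep("g", n_bc), sprintf("bc%02d", 1:n_bc),
                     rep("blue", n_bc), n_in, n_out)
  e <- allele_enrichment(ct, seed = 5)
  expect_lt(abs(e$enrichment - 2), 3 * e$sd)
  expect_gt(e$sd, 0)
})

test_that("barcode Z scores follow the printed formula", {
  # n_in = 100, E = 2, n_out = 260, beta = 1/0.35: Z = 60 / 200^0.35
  z <- epicube:::.barcode_z(100, 260, 2, 1 / 0.35)
  expect_equal(z, 60 / 200^0.35)
  expect_equal(z, 9.39, tolerance = 1e-3)
  # retained at default thresholds
  expect_lt(z, outlier_config()$c_upper)
})

test_that("planted gross outliers are rejected and clean data retained", {
  set.seed(20)
  n_bc <- 20
  alleles <- rep(sprintf("g%02d", 1:10), each = n_bc)
  bcs <- rep(sprintf("bc%02d", 1:n_bc), times = 10)
  n_in <- rpois(200, 200)
  n_out <- rpois(200, 1.5 * n_in)
  # plant one 100x outlier in the first allele
  n_out[3] <- rpois(1, 150 * n_in[3])
  ct <- counts_table(alleles, bcs, rep("blue", 200), n_in, n_out)
  res <- zscore_outlier_filter(ct)
  expect_true(any(res$rejections$allele == "g01" &
                  res$rejections$barcode == "bc03"))
  # spurious rejections on the clean remainder stay below 5%
  spurious <- res$rejections[!(res$rejections$allele == "g01" &
                               res$rejections$barcode == "bc03"), ]
  expect_lt(nrow(spurious) / 200, 0.05)
  # rejection bookkeeping is conserved
  e <- res$enrichment
  expect_equal(sum(e$n_barcodes_used) + sum(e$n_barcodes_rejected), 200)
})

test_that("clean Poisson counts pass the filter nearly untouched", {
  rejected <- vapply(1:20, function(seed) {
    set.seed(seed)
    n_in <- rpois(100, 300)
    n_out <- rpois(100, n_in * 0.8)
    ct <- counts_table(rep(sprintf("g%02d", 1:5), each = 20),
                       rep(sprintf("bc%02d", 1:20), times = 5),
                       rep("blue", 100), n_in, n_out)
    nrow(zscore_outlier_filter(ct)$rejections)
  }, numeric(1))
  expect_lt(mean(rejected) / 100, 0.05)
})

test_that("channel normalisation reproduces the published calibration", {
  ratio <- 25.0e3 / 32.4e3
  expect_equal(round(ratio, 3), 0.772)
  E <- allele_enrichment(
    counts_table(c("00", "00", "11", "11"), rep("bc1", 4),
                 c("blue", "red", "blue", "red"),
                 rep(100, 4), c(80, 1, 2, 40)), n_boot = 0)
  En <- normalize_channels(E, blue_parent = "00", red_parent = "11")
  target <- attr(En, "target_ratio")
  # the published product is 0.172; the rounded factors give 0.171
  expect_equal(target, (25.0e3 / 32.4e3) * 0.222)
  expect_lt(abs(target - 0.172), 1.5e-3)
  # red parent / blue parent ratio is now exactly the target
  e_b <- En$enrichment[En$allele == "00" & En$channel == "blue"]
  e_r <- En$enrichment[En$allele == "11" & En$channel == "red"]
  expect_equal(e_r / e_b, target)
  # identity attenuation with equal brightness and matched parents: no-op
  E2 <- allele_enrichment(
    counts_table(c("00", "00", "11", "11"), rep("bc1", 4),
                 c("blue", "red", "blue", "red"),
                 rep(100, 4), c(80, 1, 2, 80)), n_boot = 0)
  En2 <- normalize_channels(E2, "00", "11", brightness_red = 1,
                            brightness_blue = 1, red_attenuation = 1)
  expect_equal(En2$enrichment, E2$enrichment)
  # rank order within the red channel is preserved
  set.seed(2)
  ct <- counts_table(rep(sprintf("%02d", c(0, 11, 1, 10)), each = 2),
                     rep("bc1", 8),
                     rep(c("blue", "red"), 4),
                     rep(100, 8), rpois(8, 60))
  E3 <- allele_enrichment(ct, n_boot = 0)
  En3 <- normalize_channels(E3, "00", "11")
  red_before <- E3$enrichment[E3$channel == "red"]
  red_after <- En3$enrichment[En3$channel == "red"]
  expect_equal(order(red_before), order(red_after))
})

test_that("quadratic channel combination is Pythagorean and homogeneous", {
  expect_equal(combine_channels(3, 4), 5)
  expect_equal(combine_channels(0, 2.5), 2.5)
  expect_equal(combine_channels(1, 1), sqrt(2))
  expect_equal(combine_channels(2, 7), combine_channels(7, 2))
  expect_equal(combine_channels(2 * 3, 2 * 4), 2 * combine_channels(3, 4))
  expect_gte(combine_channels(3, 4), 4)
  expect_error(combine_channels(-1, 2), "nonnegative")
})

test_that("power transform recovers the generating exponent", {
  recover_alpha <- function(alpha_true, seed) {
    set.seed(seed)
    n <- 8
    o <- term_order(0:(2^n - 1), n)
    terms <- numeric(2^n)
    terms[1] <- 5
    terms[which(o == 1)] <- rnorm(n, sd = 0.5)
    terms[sample(which(o == 2), 10)] <- rnorm(10, sd = 0.4)
    y_true <- reconstruct(epistasis_spectrum(terms))$phenotypes
    y_true <- y_true - min(y_true) + 0.5
    x <- landscape(y_true^(1 / alpha_true))
    suppressWarnings(fit_power_transform(x)$alpha)
  }
  for (seed in 1:10) {
    expect_lt(abs(recover_alpha(0.5, seed) - 0.5), 0.05)
  }
  expect_lt(abs(recover_alpha(1, 3) - 1), 0.05)
  # the fitted exponent beats no transform on curved data
  set.seed(4)
  n <- 7
  terms <- numeric(2^n)
  terms[1] <- 4
  terms[2^(0:(n - 1)) + 1] <- rnorm(n, sd = 0.5)
  y_true <- reconstruct(epistasis_spectrum(terms))$phenotypes
  x <- landscape((y_true - min(y_true) + 0.5)^2)
  pt <- fit_power_transform(x)
  obj_at <- function(a) {
    y <- x$phenotypes^a
    spec <- epistasis_transform(landscape(y))
    keep <- which(term_order(0:(2^n - 1), n) <= 2) - 1
    goodness_of_fit(y, reconstruct(spec, keep)$phenotypes)$sse /
      sum((y - mean(y))^2)
  }
  expect_lte(pt$objective_value, obj_at(1) + 1e-12)
})

test_that("detection-floor pseudocounts clamp deterministically", {
  L <- landscape(c(0, 0.02, 0.5, 1))
  out <- apply_pseudocounts(L, 0.05)
  expect_equal(out$phenotypes, c(0.05, 0.05, 0.5, 1))
  # values above the floor are untouched and keep their order
  expect_equal(apply_pseudocounts(L, 0.001)$phenotypes[3:4], c(0.5, 1))
  expect_error(apply_pseudocounts(L, -1), ">= 0")
  # floor estimation from a null class
  floor_est <- estimate_detection_floor(L, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(floor_est, quantile(c(0, 0.02), 0.95, names = FALSE))
})

test_that("segment-barcode parity detects all single-base errors", {
  expect_true(validate_segment_barcode("AAAA"))
  expect_true(validate_segment_barcode("ACGT"))  # 0+1+2 = 3 -> T
  bases <- c("A", "C", "G", "T")
  for (code in c("AAAA", "ACGT", "GTCG")) {
    expect_true(validate_segment_barcode(code))
    chars <- strsplit(code, "")[[1]]
    for (pos in 1:4) {
      for (sub in setdiff(bases, chars[pos])) {
        mutated <- chars
        mutated[pos] <- sub
        expect_false(validate_segment_barcode(paste(mutated, collapse = "")))
      }
    }
  }
  expect_error(validate_segment_barcode("ACGN"), "non-ACGT")
  expect_error(validate_segment_barcode("ACG"), "4 bases")
})

test_that("counts tables validate their schema", {
  expect_error(counts_table("g", "b", "green", 1, 1), "blue")
  expect_error(counts_table("g", "b", "blue", -1, 1), "nonnegative")
  expect_error(counts_table(c("g", "g"), c("b", "b"), c("blue", "blue"),
                            c(1, 1), c(1, 1)), "unique")
})
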