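test_that("operators match their printed N=1 forms and first-principles oracle", {
  op <- build_operator(1, "background_averaged")
  expect_equal(op$omega, matrix(c(0.5, -1, 0.5, 1), 2, 2))
  op_sr <- build_operator(1, "single_reference")
  expect_equal(op_sr$omega, matrix(c(1, -1, 0, 1), 2, 2))
  for (n in 2:5) {
    expect_equal(build_operator(n, "background_averaged")$omega,
                 oracle_bg_operator(n))
    expect_equal(build_operator(n, "single_reference")$omega,
                 oracle_sr_operator(n))
  }
  # structural invariants: H H = 2^N I, V diagonal +/- (1/2)^(N-order),
  # X unit lower-triangular, and the analytic inverses invert
  for (n in c(2, 4)) {
    op <- build_operator(n, "background_averaged")
    expect_equal(op$H %*% op$H, diag(2^n) * 2^n)
    o <- term_order(0:(2^n - 1), n)
    expect_equal(diag(op$V), (-1)^o * 0.5^(n - o))
    expect_equal(op$omega_inv %*% op$omega, diag(2^n), tolerance = 1e-12)
    sr <- build_operator(n, "single_reference")
    expect_true(all(sr$X[upper.tri(sr$X)] == 0))
    expect_true(all(diag(sr$X) == 1))
    expect_equal(sr$omega_inv %*% sr$omega, diag(2^n), tolerance = 1e-12)
  }
  expect_error(build_operator(3, "nonsense"))
})

test_that("butterfly transform equals the dense operator route", {
  for (n in c(3, 6, 8)) {
    L <- random_landscape(n, seed = n)
    for (form in c("background_averaged", "single_reference")) {
      dense <- epistasis_transform(L, form, method = "dense")$terms
      fast <- epistasis_transform(L, form, method = "fast")$terms
      expect_equal(fast, dense, tolerance = 1e-10)
    }
  }
})

test_that("order-0 terms are the mean (averaged) or reference phenotype", {
  L <- random_landscape(5, seed = 11)
  expect_equal(epistasis_transform(L)$terms[1], mean(L$phenotypes))
  expect_equal(epistasis_transform(L, "single_reference")$terms[1],
               L$phenotypes[1])
  # with a shifted reference, the order-0 term is that genotype's phenotype
  spec <- epistasis_transform(L, "single_reference", reference = 13)
  expect_equal(spec$terms[1], L$phenotypes[14])
})

test_that("background-averaged first-order terms equal averaged mutation effects", {
  for (n in c(3, 5, 6)) {
    L <- random_landscape(n, seed = 100 + n)
    terms <- epistasis_transform(L)$terms
    for (p in seq_len(n)) {
      expect_equal(terms[2^(p - 1) + 1],
                   oracle_avg_effect(L$phenotypes, p, n))
    }
  }
})

test_that("additive landscapes carry no interaction terms in either form", {
  n <- 6
  set.seed(3)
  b <- rnorm(n)
  idx <- 0:(2^n - 1)
  y <- 0.4 + as.numeric(index_to_bits(idx, n) %*% b)
  L <- landscape(y)
  o <- term_order(idx, n)
  for (form in c("background_averaged", "single_reference")) {
    terms <- epistasis_transform(L, form)$terms
    expect_lt(max(abs(terms[o >= 2])), 1e-12)
  }
})

test_that("reconstruction inverts the transform and supports term subsets", {
  L <- random_landscape(7, seed = 21)
  for (form in c("background_averaged", "single_reference")) {
    spec <- epistasis_transform(L, form)
    expect_equal(reconstruct(spec)$phenotypes, L$phenotypes,
                 tolerance = 1e-10)
  }
  spec <- epistasis_transform(L)
  # order-0 only: constant at the mean
  expect_equal(reconstruct(spec, keep = 0)$phenotypes,
               rep(mean(L$phenotypes), 128))
  # empty keep: all-zero phenotypes
  expect_equal(reconstruct(spec, keep = integer(0))$phenotypes, rep(0, 128))
  # planted sparse spectrum: keeping exactly the support is exact
  sim <- simulate_sparse_landscape(synthetic_spec(6, 5, seed = 4))
  support <- which(sim$truth$terms != 0) - 1
  spec6 <- epistasis_transform(sim$landscape)
  expect_equal(reconstruct(spec6, keep = support)$phenotypes,
               sim$landscape$phenotypes, tolerance = 1e-10)
})

test_that("goodness of fit follows the R^2 and GoP definitions", {
  y <- c(0, 1, 2, 4)
  expect_equal(goodness_of_fit(y, y)$r_squared, 1)
  expect_equal(goodness_of_fit(y, y)$gop, 1)
  gm <- goodness_of_fit(y, rep(mean(y), 4))
  expect_equal(gm$r_squared, 0)
  expect_equal(gm$gop, 0.5)
  # hand-computed: y=(0,1), yhat=(1,0): SSE=2, SST=0.5, R^2=-3
  g <- goodness_of_fit(c(0, 1), c(1, 0))
  expect_equal(g$r_squared, -3)
  expect_equal(g$gop, 1 / (1 + 4))
  expect_error(goodness_of_fit(c(1, 1), c(1, 2)), "constant")
})

test_that("term contributions are orthogonal, additive and correctly ranked", {
  n <- 5
  L <- random_landscape(n, seed = 31)
  spec <- epistasis_transform(L)
  inv <- build_operator(n, "background_averaged")$omega_inv
  # columns of the inverse are mutually orthogonal
  gram <- crossprod(inv)
  expect_equal(gram, diag(diag(gram)), tolerance = 1e-12)
  # SSE of a reconstruction equals the summed contributions left out
  ctr <- term_contributions(spec)
  keep <- c(0, 3, 17, 30)
  sse <- goodness_of_fit(L, reconstruct(spec, keep))$sse
  expect_equal(sse, sum(ctr[-(keep + 1)]), tolerance = 1e-10)
  # ranking matches greedy forward selection by SSE
  expect_equal(rank_terms(spec), oracle_greedy_rank(spec, n))
  # nested R^2 is non-decreasing and reaches 1 with all terms
  ranked <- rank_terms(spec)
  r2 <- vapply(seq_len(2^n), function(k) {
    goodness_of_fit(L, reconstruct(spec, ranked[seq_len(k)]))$r_squared
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
  expect_equal(r2[2^n], 1)
})

test_that("rank_terms puts a planted high-order term first", {
  n <- 6
  terms <- numeric(2^n)
  terms[1] <- 0.2
  planted <- genotype_index(c(1, 1, 1, 0, 0, 0))  # an order-3 term
  terms[planted + 1] <- 2
  y <- reconstruct(epistasis_spectrum(terms))$phenotypes
  set.seed(8)
  spec <- epistasis_transform(landscape(y + rnorm(2^n, sd = 0.01)))
  expect_equal(rank_terms(spec)[1], planted)
})

test_that("rereferencing is an XOR involution matching local epistasis", {
  L <- random_landscape(4, seed = 41)
  expect_equal(rereference(L, 0)$phenotypes, L$phenotypes)
  expect_equal(rereference(rereference(L, 9), 9)$phenotypes, L$phenotypes)
  L2 <- random_landscape(2, seed = 5)
  expect_equal(rereference(L2, 3)$phenotypes[1], L2$phenotypes[4])
  # first-order term relative to reference r equals a direct difference
  r <- 5
  spec <- epistasis_transform(L, "single_reference", reference = r)
  p <- 2  # position 2 (bit 1); reference has bit 1 set -> flipping clears it
  flipped <- ifelse(r %/% 2^(p - 1) %% 2 == 1, r - 2^(p - 1), r + 2^(p - 1))
  expect_equal(spec$terms[2^(p - 1) + 1],
               L$phenotypes[flipped + 1] - L$phenotypes[r + 1])
})

test_that("fast transform of N=12 landscapes is immediate", {
  L <- random_landscape(12, seed = 51)
  elapsed <- system.time(fast_transform(L))["elapsed"]
  expect_lt(elapsed, 1)
})

test_that("landscape constructor validates its input", {
  expect_error(landscape(c(1, 2, 3)), "2\\^N")
  expect_error(landscape(c(1, NA, 2, 3)), "finite")
  expect_error(landscape(1:4, noise_sd = c(-1, 1, 1, 1)), "nonnegative")
  expect_error(epistasis_transform(landscape(1:4), "unknown_form"))
})
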