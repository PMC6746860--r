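test_that("functional adjacency thresholds nodes correctly", {
  L <- landscape(c(1, 1, 0, 1))
  adj <- functional_adjacency(L, 0.5)
  expect_equal(adj$functional_indices, c(0, 1, 3))
  expect_error(functional_adjacency(L, 2), "threshold")
  # below-minimum threshold keeps the full hypercube
  L2 <- unit_landscape(4)
  expect_length(functional_adjacency(L2, 0.5)$functional_indices, 16)
})

test_that("path counts on full cubes equal factorials for antipodal walks", {
  for (n in c(3, 5, 8)) {
    adj <- functional_adjacency(unit_landscape(n), 0.5)
    expect_equal(count_paths(adj, 0, 2^n - 1, n), factorial(n))
  }
  adj3 <- functional_adjacency(unit_landscape(3), 0.5)
  expect_equal(count_paths(adj3, 0, 7, 3), 6)
  expect_error(count_paths(adj3, 0, 7, -1), "nonnegative")
})

test_that("path counts match exhaustive DFS enumeration on pruned cubes", {
  n <- 4
  for (seed in 1:20) {
    set.seed(seed)
    y <- rep(1, 2^n)
    dead <- sample(1:(2^n - 2), 3)  # never the antipodes
    y[dead + 1] <- 0
    L <- landscape(y)
    adj <- functional_adjacency(L, 0.5)
    mask <- adj$functional_mask
    for (m in c(2, 4)) {
      expect_equal(count_paths(adj, 0, 2^n - 1, m),
                   oracle_count_walks(mask, n, 0, 2^n - 1, m))
    }
  }
})

test_that("raising the threshold never increases path counts", {
  set.seed(14)
  n <- 5
  y <- runif(2^n)
  y[1] <- y[2^n] <- 1  # keep the antipodes functional throughout
  L <- landscape(y)
  thresholds <- c(0.1, 0.3, 0.5, 0.7)
  counts <- vapply(thresholds, function(th) {
    count_paths(functional_adjacency(L, th), 0, 2^n - 1, n)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  fracs <- vapply(thresholds, function(th) {
    sum(step_connectivity(functional_adjacency(L, th))$fraction)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 1e-12))
})

test_that("connectograms partition functional genotypes into components", {
  # full cube: one component
  adj <- functional_adjacency(unit_landscape(4), 0.5)
  cg <- connectogram(adj)
  expect_equal(cg$n_components, 1)
  expect_setequal(cg$ordering, adj$functional_indices)
  # two functional nodes at Hamming distance 2, no intermediate
  L <- landscape(c(1, 0, 0, 1))
  cg2 <- connectogram(functional_adjacency(L, 0.5))
  expect_equal(cg2$n_components, 2)
  # components partition all functional nodes
  set.seed(4)
  L3 <- landscape(runif(64))
  adj3 <- functional_adjacency(L3, 0.5)
  cg3 <- connectogram(adj3)
  expect_length(cg3$components, length(adj3$functional_indices))
  expect_setequal(cg3$ordering, adj3$functional_indices)
})

test_that("layer fractions match direct-path enumeration on random prunings", {
  n <- 5
  for (seed in 1:20) {
    L <- simulate_two_parent_landscape(n, ruggedness = 0.5, seed = seed)
    adj <- functional_adjacency(L, 0.73)
    sc <- step_connectivity(adj)
    oracle <- oracle_direct_paths(adj$functional_mask, n)
    expect_equal(attr(sc, "n_direct_paths"), oracle$n_paths)
    layer <- term_order(0:(2^n - 1), n)
    for (k in 0:n) {
      expect_equal(sc$n_on_path[k + 1], sum(oracle$on_path[layer == k]))
    }
  }
})

test_that("step connectivity endpoints reflect direct-path existence", {
  # fully functional cube: all fractions 1
  sc <- step_connectivity(functional_adjacency(unit_landscape(4), 0.5))
  expect_equal(sc$fraction, rep(1, 5))
  # single surviving direct path: interior fractions 1 / choose(N, k)
  n <- 4
  y <- rep(0, 2^n)
  path_nodes <- c(0, cumsum(2^(c(2, 0, 3, 1))))
  y[path_nodes + 1] <- 1
  sc1 <- step_connectivity(functional_adjacency(landscape(y), 0.5))
  expect_equal(sc1$fraction, 1 / choose(n, 0:n))
  expect_equal(attr(sc1, "n_direct_paths"), 1)
  # severed middle: no direct paths, endpoint fractions 0
  y2 <- rep(1, 8)
  y2[c(1, 2, 4) + 1] <- 0  # kill the whole first layer of the 3-cube
  sc2 <- step_connectivity(functional_adjacency(landscape(y2), 0.5))
  expect_equal(attr(sc2, "n_direct_paths"), 0)
  expect_equal(sc2$fraction[c(1, 4)], c(0, 0))
  expect_error(
    step_connectivity(functional_adjacency(unit_landscape(3), 0.5), 0, 3),
    "antipodal")
})

test_that("pairwise epistasis classes follow the sign table", {
  # reciprocal sign: both mutations deleterious alone, beneficial jointly
  L <- landscape(c(0, -0.5, -0.5, 1))
  expect_equal(classify_pairwise(L, 1, 2)$class, "reciprocal_sign")
  # additive square: no epistasis
  L2 <- landscape(c(0, 0.3, 0.5, 0.8))
  expect_equal(classify_pairwise(L2, 1, 2)$class, "no_epistasis")
  # sign: effect of position 1 flips with position 2
  L3 <- landscape(c(0, 0.2, 1, 0.5))
  expect_equal(classify_pairwise(L3, 1, 2)$class, "sign")
  # magnitude: same sign, different size
  L4 <- landscape(c(0, 0.2, 0.5, 1.2))
  expect_equal(classify_pairwise(L4, 1, 2)$class, "magnitude")
  expect_error(classify_pairwise(L4, 1, 2, background = 1), "clear")
  expect_error(classify_pairwise(L4, 1, 1), "distinct")
})

test_that("background aggregation reports fractions and the modal class", {
  # landscape additive in positions 1,2 but modulated by position 3
  y <- c(0, 0.3, 0.5, 0.8,   0, -0.5, -0.5, 1)
  L <- landscape(y)
  agg <- classify_pair_all_backgrounds(L, 1, 2)
  expect_equal(agg$n_backgrounds, 2)
  expect_equal(sum(agg$fractions), 1)
  expect_equal(agg$fractions[["no_epistasis"]], 0.5)
  expect_equal(agg$fractions[["reciprocal_sign"]], 0.5)
})

test_that("ruggedness prunes paths monotonically in the median", {
  n <- 6
  med_paths <- vapply(c(0, 0.5, 1), function(r) {
    counts <- vapply(1:20, function(seed) {
      L <- simulate_two_parent_landscape(n, r, seed = seed)
      count_paths(functional_adjacency(L, 0.73), 0, 2^n - 1, n)
    }, numeric(1))
    median(counts)
  }, numeric(1))
  expect_true(all(diff(med_paths) <= 0))
  expect_equal(med_paths[1], factorial(n))
})

test_that("edge lists serialise functional edges symmetrically once", {
  L <- landscape(c(1, 1, 0, 1))
  adj <- functional_adjacency(L, 0.5)
  path <- tempfile(fileext = ".tsv")
  write_edge_list(adj, path)
  edges <- read.delim(path)
  expect_equal(nrow(edges), 2)  # 0-1 and 1-3
  expect_true(all(edges$from < edges$to))
  unlink(path)
})
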