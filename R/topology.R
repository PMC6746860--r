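# Functional-genotype adjacency, trajectory counting by step propagation,
# connectivity structure, and classification of pairwise epistasis severity.

#' Adjacency structure of above-threshold genotypes
#'
#' Nodes are genotypes with phenotype strictly above `threshold`; edges link
#' functional genotypes at Hamming distance one (single mutations). This is
#' the binarisation of the full hypercube adjacency restricted to functional
#' genotypes.
#'
#' @param L a [landscape()].
#' @param threshold selection threshold (strict `>`); default 0.73, the
#'   minimal parental brightness in the motivating blue/red system.
#' @return object of class `functional_adjacency`: list with `n_positions`,
#'   `threshold`, `functional_indices` (0-based), `functional_mask` (logical
#'   over all `2^N`).
#' @export
functional_adjacency <- function(L, threshold = 0.73) {
  stopifnot(inherits(L, "landscape"))
  n <- L$n_positions
  mask <- L$phenotypes > threshold
  if (!any(mask)) stop("no genotypes exceed threshold ", threshold)
  structure(
    list(n_positions = n, threshold = threshold,
         functional_indices = which(mask) - 1L, functional_mask = mask),
    class = "functional_adjacency"
  )
}

#' @export
print.functional_adjacency <- function(x, ...) {
  cat("functional adjacency: N =", x$n_positions, "|",
      length(x$functional_indices), "of", 2^x$n_positions,
      "genotypes above threshold", x$threshold, "\n")
  invisible(x)
}

# one step of walk-count propagation over functional edges:
# v'[g] = sum over Hamming neighbors h of v[h], then restricted to
# functional g. Implemented as N vectorised XOR-permutations.
.propagate_step <- function(v, n_positions, mask) {
  len <- length(v)
  out <- numeric(len)
  idx <- seq_len(len) - 1
  for (k in seq_len(n_positions) - 1L) {
    bit <- idx %/% 2^k %% 2
    nbr <- idx + (1 - 2 * bit) * 2^k
    out <- out + v[nbr + 1L]
  }
  out[!mask] <- 0
  out
}

#' Count functional m-step trajectories between two genotypes
#'
#' The (source, target) element of the m-th power of the functional
#' adjacency matrix: the number of m-step walks in which every visited
#' genotype is functional. Computed by sparse per-step vector propagation,
#' never materialising matrix powers. For an antipodal pair with
#' `m = N` (the Hamming distance), walks coincide with direct paths, so
#' this is the number of functional single-step trajectories; for larger
#' `m`, walks may revisit genotypes. Counts are exact while below 2^53
#' (double-precision integer range), which covers the 13! ~ 6.2e9 scale of
#' full-cube direct paths with ample headroom.
#'
#' @param adj a [functional_adjacency()].
#' @param source,target genotype indices (must be functional).
#' @param m number of steps, `>= 0`.
#' @return numeric count of functional m-step trajectories.
#' @examples
#' # on the full 3-cube there are 3! = 6 direct paths between antipodes
#' L <- landscape(rep(1, 8))
#' count_paths(functional_adjacency(L, 0.5), 0, 7, 3)  # 6
#' @export
count_paths <- function(adj, source, target, m) {
  stopifnot(inherits(adj, "functional_adjacency"))
  n <- adj$n_positions
  source <- .check_index(source, n)
  target <- .check_index(target, n)
  if (length(m) != 1L || m < 0 || m != floor(m)) {
    stop("`m` must be a nonnegative integer")
  }
  if (!adj$functional_mask[source + 1L] || !adj$functional_mask[target + 1L]) {
    stop("source and target must both be functional genotypes")
  }
  v <- numeric(2^n)
  v[source + 1L] <- 1
  for (step in seq_len(m)) {
    v <- .propagate_step(v, n, adj$functional_mask)
  }
  v[target + 1L]
}

#' Connectivity structure of the functional subgraph
#'
#' Summing adjacency powers up to `M` gives reachability within `M` or fewer
#' steps; ordering genotypes so that mutually reachable ones are contiguous
#' puts that summed matrix in block form — a "genotypic connectogram". When
#' `M` is at least the subgraph diameter the blocks are exactly the
#' connected components.
#'
#' @param adj a [functional_adjacency()].
#' @param M maximum number of steps; default `2^N` (>= any diameter, so
#'   blocks = connected components).
#' @return list with `components` (integer component id per functional
#'   genotype, named by 0-based index), `n_components`, `ordering`
#'   (functional indices ordered by component then mutational layer), `M`.
#' @export
connectogram <- function(adj, M = NULL) {
  stopifnot(inherits(adj, "functional_adjacency"))
  n <- adj$n_positions
  if (is.null(M)) M <- 2^n
  if (M < 1) stop("`M` must be >= 1")
  fidx <- adj$functional_indices
  pos <- match(seq_len(2^n) - 1L, fidx)  # map genotype index -> node number
  edges <- integer(0)
  for (g in fidx) {
    nb <- hamming_neighbors(g, n)
    nb <- nb[adj$functional_mask[nb + 1L] & nb > g]
    if (length(nb)) edges <- c(edges, rbind(pos[g + 1L], pos[nb + 1L]))
  }
  gr <- igraph::make_empty_graph(n = length(fidx), directed = FALSE)
  if (length(edges)) gr <- igraph::add_edges(gr, edges)
  # components within <= M steps: cap geodesic distance at M
  if (M >= length(fidx)) {
    comp <- igraph::components(gr)$membership
  } else {
    d <- igraph::distances(gr)
    reach <- is.finite(d) & d <= M
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(reach, mode = "undirected",
                                          diag = FALSE))$membership
  }
  ord <- fidx[order(comp, term_order(fidx, n), fidx)]
  list(components = stats::setNames(as.integer(comp), fidx),
       n_components = max(comp), ordering = ord, M = M)
}

#' Fraction of each mutational layer lying on a functional direct path
#'
#' For an antipodal source/target pair, a direct path flips each differing
#' position exactly once (length `N`). Two directional dynamic-programming
#' passes count, for every genotype `g`, the functional direct paths
#' source -> g and g -> target; a genotype is "on-path" if both counts are
#' positive. Layer `k`'s fraction has denominator `choose(N, k)` — all
#' genotypes of the layer, functional or not.
#'
#' @param adj a [functional_adjacency()].
#' @param source,target antipodal functional genotypes (differ at all `N`
#'   positions).
#' @return data.frame with columns `layer`, `n_layer`, `n_on_path`,
#'   `fraction`, plus attribute `n_direct_paths` (total functional direct
#'   paths source -> target).
#' @export
step_connectivity <- function(adj, source = 0,
                              target = 2^adj$n_positions - 1) {
  stopifnot(inherits(adj, "functional_adjacency"))
  n <- adj$n_positions
  source <- .check_index(source, n)
  target <- .check_index(target, n)
  if (.xor_index(source, target, n) != 2^n - 1) {
    stop("`source` and `target` must be antipodal (differ at all positions)")
  }
  if (!adj$functional_mask[source + 1L] || !adj$functional_mask[target + 1L]) {
    stop("source and target must both be functional genotypes")
  }
  # re-label so source = 0, target = all-ones; direct paths become monotone
  idx <- seq_len(2^n) - 1
  relab <- vapply(idx, function(i) .xor_index(i, source, n), numeric(1))
  mask <- logical(2^n)
  mask[relab + 1L] <- adj$functional_mask[idx + 1L]
  layer <- term_order(idx, n)

  up <- numeric(2^n)    # functional monotone path counts source -> g
  up[1L] <- 1
  for (k in seq_len(n)) {
    for (g in idx[layer == k]) {
      if (!mask[g + 1L]) next
      below <- hamming_neighbors(g, n)
      below <- below[layer[below + 1L] == k - 1L]
      up[g + 1L] <- sum(up[below + 1L])
    }
  }
  down <- numeric(2^n)  # functional monotone path counts g -> target
  down[2^n] <- 1
  for (k in rev(seq_len(n)) - 1L) {
    for (g in idx[layer == k]) {
      if (!mask[g + 1L]) next
      above <- hamming_neighbors(g, n)
      above <- above[layer[above + 1L] == k + 1L]
      down[g + 1L] <- sum(down[above + 1L])
    }
  }
  on_path <- up > 0 & down > 0
  out <- data.frame(
    layer = 0:n,
    n_layer = choose(n, 0:n),
    n_on_path = vapply(0:n, function(k) sum(on_path[layer == k]), numeric(1))
  )
  out$fraction <- out$n_on_path / out$n_layer
  attr(out, "n_direct_paths") <- up[2^n] * 1  # == down[1] as well
  out
}

#' Classify pairwise epistasis in one genetic background
#'
#' On the 2x2 sub-square spanned by positions `i`, `j` over a background
#' with both bits clear, compare the effect of mutation `i` in the two `j`
#' states (`a1 = y10 - y00`, `a2 = y11 - y01`) and vice versa
#' (`b1 = y01 - y00`, `b2 = y11 - y10`). Both effects flipping sign is
#' reciprocal sign epistasis, exactly one is sign epistasis, neither (with
#' unequal effects) is magnitude epistasis, and equal effects (within
#' `tol`) mean no epistasis. Sign and reciprocal-sign epistasis are the
#' severe forms that can strand single-step evolutionary trajectories below
#' a selection threshold.
#'
#' @param L a [landscape()].
#' @param i,j positions (1-based, distinct).
#' @param background genotype index with bits `i` and `j` clear.
#' @param tol tolerance for sign/equality comparisons (default 1e-9).
#' @return object of class `pair_class`: list with `pair`, `background`,
#'   `class` (one of `"no_epistasis"`, `"magnitude"`, `"sign"`,
#'   `"reciprocal_sign"`), and the four sub-square phenotypes.
#' @export
classify_pairwise <- function(L, i, j, background = 0, tol = 1e-9) {
  stopifnot(inherits(L, "landscape"))
  n <- L$n_positions
  if (i == j || i < 1 || j < 1 || i > n || j > n) {
    stop("`i` and `j` must be distinct positions in 1..N")
  }
  background <- .check_index(background, n)
  bi <- 2^(i - 1)
  bj <- 2^(j - 1)
  if (background %/% bi %% 2 != 0 || background %/% bj %% 2 != 0) {
    stop("`background` must have bits i and j clear")
  }
  y00 <- L$phenotypes[background + 1L]
  y10 <- L$phenotypes[background + bi + 1L]
  y01 <- L$phenotypes[background + bj + 1L]
  y11 <- L$phenotypes[background + bi + bj + 1L]
  a1 <- y10 - y00; a2 <- y11 - y01
  b1 <- y01 - y00; b2 <- y11 - y10
  sgn <- function(x) if (abs(x) <= tol) 0 else sign(x)
  flip_a <- sgn(a1) != sgn(a2)
  flip_b <- sgn(b1) != sgn(b2)
  cls <- if (flip_a && flip_b) "reciprocal_sign"
         else if (flip_a || flip_b) "sign"
         else if (abs(a1 - a2) > tol) "magnitude"
         else "no_epistasis"
  structure(
    list(pair = c(i = i, j = j), background = background, class = cls,
         phenotypes = c(y00 = y00, y10 = y10, y01 = y01, y11 = y11),
         effects = c(a1 = a1, a2 = a2, b1 = b1, b2 = b2)),
    class = "pair_class"
  )
}

#' @export
print.pair_class <- function(x, ...) {
  cat(sprintf("pair (%d, %d) in background %d: %s\n",
              x$pair["i"], x$pair["j"], x$background, x$class))
  invisible(x)
}

#' Aggregate pairwise epistasis classes over all backgrounds
#'
#' Classifies the `(i, j)` sub-square in every background with both bits
#' clear and reports the fraction of backgrounds per class plus the modal
#' class. Two aggregations of the "severe epistasis" statistic are thereby
#' available: per-background fractions, and the modal class per pair.
#'
#' @inheritParams classify_pairwise
#' @return list with `fractions` (named, over the four classes), `modal`
#'   (modal class), `n_backgrounds`.
#' @export
classify_pair_all_backgrounds <- function(L, i, j, tol = 1e-9) {
  n <- L$n_positions
  bi <- 2^(i - 1); bj <- 2^(j - 1)
  idx <- seq_len(2^n) - 1
  bgs <- idx[idx %/% bi %% 2 == 0 & idx %/% bj %% 2 == 0]
  classes <- vapply(bgs, function(b) {
    classify_pairwise(L, i, j, b, tol)$class
  }, character(1))
  levels <- c("no_epistasis", "magnitude", "sign", "reciprocal_sign")
  frac <- table(factor(classes, levels = levels)) / length(bgs)
  list(fractions = stats::setNames(as.numeric(frac), levels),
       modal = names(which.max(table(factor(classes, levels = levels)))),
       n_backgrounds = length(bgs))
}

#' Export functional edges as a TSV edge list
#'
#' @param adj a [functional_adjacency()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(adj, path) {
  stopifnot(inherits(adj, "functional_adjacency"))
  n <- adj$n_positions
  from <- to <- numeric(0)
  for (g in adj$functional_indices) {
    nb <- hamming_neighbors(g, n)
    nb <- nb[adj$functional_mask[nb + 1L] & nb > g]
    if (length(nb)) {
      from <- c(from, rep(g, length(nb)))
      to <- c(to, nb)
    }
  }
  utils::write.table(
    data.frame(from = from, to = to,
               from_genotype = format_genotype(from, n),
               to_genotype = format_genotype(to, n)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
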