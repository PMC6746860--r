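# Synthetic genotype-phenotype landscapes and FACS-seq count tables with
# the statistical structure the analysis pipeline assumes, providing
# ground truth for every stage: sparse high-order spectra inverted to
# phenotypes with additive Gaussian noise, and barcode counts from
# top-percentile gating of near log-normal per-cell fluorescence.

#' Specification for a sparse synthetic landscape
#'
#' @param n_positions number of positions `N`.
#' @param n_terms number of nonzero interaction terms `K` (order >= 1);
#'   an order-0 offset is always included.
#' @param order_weights sampling weights over orders `1..N`; default a
#'   discretised unimodal curve peaking at order 3-4, the shape typical of
#'   empirically observed high-order interaction spectra.
#' @param magnitude one of `"fixed"`, `"normal"`, `"laplace"`.
#' @param scale magnitude scale.
#' @param noise_sd additive Gaussian measurement noise SD on phenotypes.
#' @param offset order-0 term (mean phenotype level).
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_positions, n_terms, order_weights = NULL,
                           magnitude = c("normal", "fixed", "laplace"),
                           scale = 1, noise_sd = 0, offset = 0, seed = 1L) {
  n <- .check_n(n_positions)
  magnitude <- match.arg(magnitude)
  if (n_terms < 0 || n_terms > 2^n - 1) {
    stop("`n_terms` must be in [0, 2^N - 1]")
  }
  if (is.null(order_weights)) {
    # unimodal over orders 1..N, peaking at order 3-4
    o <- seq_len(n)
    order_weights <- stats::dnorm(o, mean = 3.5, sd = 1.5)
  }
  if (length(order_weights) != n || any(order_weights < 0) ||
      sum(order_weights) <= 0) {
    stop("`order_weights` must be N nonnegative weights with positive sum")
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(
    list(n_positions = n, n_terms = as.integer(n_terms),
         order_weights = order_weights, magnitude = magnitude,
         scale = scale, noise_sd = noise_sd, offset = offset,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Simulate a landscape with a planted sparse epistatic spectrum
#'
#' Draws `K` distinct nonzero term indices with order probabilities
#' proportional to the order weights, draws magnitudes, and inverts the
#' background-averaged transform to phenotypes, adding Gaussian measurement
#' noise. The noiseless transform of the output recovers the planted
#' spectrum exactly.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `landscape` (a [landscape()], `noise_sd` attached when
#'   positive) and `truth` (the planted [epistasis_spectrum()]).
#' @export
simulate_sparse_landscape <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_positions
  set.seed(spec$seed)
  terms <- numeric(2^n)
  terms[1L] <- spec$offset
  if (spec$n_terms > 0) {
    idx <- seq_len(2^n - 1)  # candidate indices 1 .. 2^N-1
    o <- term_order(idx, n)
    prob <- spec$order_weights[o] / choose(n, o)  # per-index weight
    chosen <- sample(idx, spec$n_terms, prob = prob)
    mag <- switch(spec$magnitude,
      fixed = rep(spec$scale, spec$n_terms) *
        sample(c(-1, 1), spec$n_terms, replace = TRUE),
      normal = stats::rnorm(spec$n_terms, sd = spec$scale),
      laplace = spec$scale * sample(c(-1, 1), spec$n_terms, replace = TRUE) *
        stats::rexp(spec$n_terms)
    )
    # guard against exact zeros, which would shrink the true support
    mag[mag == 0] <- spec$scale
    terms[chosen + 1L] <- mag
  }
  y <- .inverse_terms(terms, n, "background_averaged")
  if (spec$noise_sd > 0) y <- y + stats::rnorm(2^n, sd = spec$noise_sd)
  list(
    landscape = landscape(y, noise_sd = if (spec$noise_sd > 0)
      rep(spec$noise_sd, 2^n) else NULL),
    truth = epistasis_spectrum(terms, form = "background_averaged")
  )
}

#' Specification for a simulated FACS-seq counts experiment
#'
#' @param barcodes_per_allele uniqueness barcodes per allele (default 20).
#' @param total_input_reads total input-library reads per channel
#'   (default 1e6).
#' @param gate_fraction sort gate: top fraction of the cell population
#'   recovered (default 0.01, a top-1% gate).
#' @param percell_lognormal_sd SD of per-cell log fluorescence around the
#'   allele brightness (default 0.5).
#' @param outlier_rate fraction of barcodes planted as outliers (default 0).
#' @param outlier_multiplier factor applied to a planted outlier's expected
#'   output counts (default 100).
#' @param red_bit position (1-based) whose mutant allele is required for red
#'   fluorescence, mimicking a chromophore mutation (default 3).
#' @param red_co_bits positions additionally required for red (default
#'   none); a genotype is red iff all required bits are 1. Purely a fixture
#'   convention.
#' @param seed integer seed.
#' @return list of class `counts_sim_spec`.
#' @export
counts_sim_spec <- function(barcodes_per_allele = 20L,
                            total_input_reads = 1e6,
                            gate_fraction = 0.01,
                            percell_lognormal_sd = 0.5,
                            outlier_rate = 0,
                            outlier_multiplier = 100,
                            red_bit = 3L, red_co_bits = integer(0),
                            seed = 1L) {
  if (gate_fraction <= 0 || gate_fraction >= 1) {
    stop("`gate_fraction` must be in (0, 1)")
  }
  if (outlier_rate < 0 || outlier_rate > 1) {
    stop("`outlier_rate` must be in [0, 1]")
  }
  structure(
    list(barcodes_per_allele = as.integer(barcodes_per_allele),
         total_input_reads = total_input_reads,
         gate_fraction = gate_fraction,
         percell_lognormal_sd = percell_lognormal_sd,
         outlier_rate = outlier_rate,
         outlier_multiplier = outlier_multiplier,
         red_bit = as.integer(red_bit),
         red_co_bits = as.integer(red_co_bits),
         seed = as.integer(seed)),
    class = "counts_sim_spec"
  )
}

# expected probability that a cell of log-mean brightness b passes a gate
# set at the top `gate_fraction` of the whole population
.gate_pass_prob <- function(brightness, gate, sdlog) {
  ifelse(brightness <= 0, 0,
         stats::pnorm((log(brightness) - log(gate)) / sdlog))
}

#' Simulate a two-channel FACS-seq counts experiment
#'
#' Per allele and channel: input reads are multinomial over uniqueness
#' barcodes; each cell's fluorescence is log-normal around the allele's
#' channel brightness; the sorter gate sits at the population quantile
#' recovering the top `gate_fraction` of cells in that channel, so an
#' allele's sort-pass probability is its upper-tail mass beyond the gate;
#' output counts are Poisson around `pass_prob x input / gate_fraction`
#' (re-sequencing the sorted pool at input depth). Planted outlier barcodes
#' have their expected output multiplied by `outlier_multiplier`; they are
#' planted only in an allele's active channel, mimicking mis-sorting and
#' spurious-mutation events among the reads that actually exist. The
#' channel split assigns a genotype's brightness to the red channel iff the
#' chromophore bit (and any co-required bits) carry the mutant allele, else
#' to the blue channel; the dark channel is truly dark (zero expected
#' output).
#'
#' @param L a [landscape()] of true (nonnegative) brightness values.
#' @param spec a [counts_sim_spec()].
#' @return list with `counts` (a [counts_table()]), `outliers` (data.frame
#'   of planted outlier barcodes), `truth` (per-allele data.frame:
#'   genotype, brightness, is_red, channel brightnesses).
#' @export
simulate_counts_experiment <- function(L, spec) {
  stopifnot(inherits(L, "landscape"), inherits(spec, "counts_sim_spec"))
  if (any(L$phenotypes < 0)) stop("brightness values must be nonnegative")
  n <- L$n_positions
  set.seed(spec$seed)
  idx <- seq_len(2^n) - 1
  genotypes <- format_genotype(idx, n)
  req_bits <- c(spec$red_bit, spec$red_co_bits)
  is_red <- rep(TRUE, 2^n)
  for (b in req_bits) is_red <- is_red & (idx %/% 2^(b - 1) %% 2 == 1)
  bright <- data.frame(
    genotype = genotypes,
    brightness = L$phenotypes,
    is_red = is_red,
    blue = ifelse(is_red, 0, L$phenotypes),
    red = ifelse(is_red, L$phenotypes, 0),
    stringsAsFactors = FALSE
  )
  nb <- spec$barcodes_per_allele
  rows <- vector("list", 2L)
  outlier_rows <- list()
  for (ch in c("blue", "red")) {
    b_ch <- bright[[ch]]
    # population gate: top gate_fraction of all cells in this channel,
    # cells contributed equally per allele
    draws <- exp(log(pmax(b_ch, 1e-12)) +
                   stats::rnorm(2^n * 50, sd = spec$percell_lognormal_sd))
    gate <- stats::quantile(draws, 1 - spec$gate_fraction, names = FALSE)
    pass <- .gate_pass_prob(b_ch, gate, spec$percell_lognormal_sd)
    # input reads: uniform across alleles, multinomial across barcodes
    n_allele <- as.numeric(
      stats::rmultinom(1L, spec$total_input_reads, rep(1, 2^n)))
    allele_col <- rep(genotypes, each = nb)
    n_in <- as.numeric(vapply(n_allele, function(m) {
      stats::rmultinom(1L, m, rep(1, nb))
    }, numeric(nb)))
    lambda <- rep(pass, each = nb) * n_in / spec$gate_fraction
    active <- rep(b_ch > 0, each = nb)
    is_out <- active & stats::runif(length(n_in)) < spec$outlier_rate
    lambda[is_out] <- lambda[is_out] * spec$outlier_multiplier
    n_out <- stats::rpois(length(lambda), lambda)
    barcode <- rep(sprintf("bc%03d", seq_len(nb)), times = 2^n)
    rows[[ch]] <- data.frame(
      allele = allele_col, barcode = barcode, channel = ch,
      n_in = n_in, n_out = n_out, stringsAsFactors = FALSE
    )
    if (any(is_out)) {
      outlier_rows[[ch]] <- data.frame(
        allele = allele_col[is_out], barcode = barcode[is_out], channel = ch,
        stringsAsFactors = FALSE
      )
    }
  }
  counts <- do.call(rbind, rows)
  counts <- counts_table(counts$allele, counts$barcode, counts$channel,
                         counts$n_in, counts$n_out)
  list(
    counts = counts,
    outliers = if (length(outlier_rows)) do.call(rbind, outlier_rows)
               else data.frame(allele = character(0), barcode = character(0),
                               channel = character(0)),
    truth = bright
  )
}

#' Simulate a two-parent landscape with tunable ruggedness
#'
#' A harness for connectivity analyses: both antipodal parents are
#' functional at the configured threshold, and `ruggedness` interpolates
#' between a smooth fully functional landscape (0) and a heavily pruned
#' dumbbell (1) in which intermediate layers are mostly non-functional —
#' pruning probability peaks at the middle layers, where combinatorial
#' intermediates are most numerous. With `connectivity_guard = TRUE`
#' (default) one random direct path is kept functional, so the parents stay
#' connected; with the guard off, full pruning can disconnect them.
#'
#' @param n_positions number of positions `N`.
#' @param ruggedness in `[0, 1]`.
#' @param seed integer seed.
#' @param threshold functional threshold the landscape is built around
#'   (default 0.73).
#' @param connectivity_guard keep one direct path functional (default TRUE).
#' @return a [landscape()]; functional genotypes sit near 0.9, pruned ones
#'   near 0.2.
#' @export
simulate_two_parent_landscape <- function(n_positions, ruggedness, seed,
                                          threshold = 0.73,
                                          connectivity_guard = TRUE) {
  n <- .check_n(n_positions)
  if (ruggedness < 0 || ruggedness > 1) stop("`ruggedness` must be in [0, 1]")
  set.seed(as.integer(seed))
  idx <- seq_len(2^n) - 1
  layer <- term_order(idx, n)
  functional <- rep(TRUE, 2^n)
  # prune interior genotypes with probability peaking mid-cube
  interior <- idx != 0 & idx != 2^n - 1
  p_prune <- ruggedness * (layer * (n - layer)) / (n^2 / 4)
  functional[interior] <- stats::runif(sum(interior)) >=
    p_prune[interior]
  if (connectivity_guard) {
    path_nodes <- cumsum(2^(sample.int(n) - 1))  # one random direct path
    functional[c(1L, path_nodes + 1L)] <- TRUE
  }
  y <- ifelse(functional,
              threshold + 0.17 + stats::runif(2^n, -0.05, 0.05),
              threshold - 0.5 + stats::runif(2^n, -0.05, 0.05))
  y <- pmax(y, 0)
  landscape(y)
}
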