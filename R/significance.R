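# Error propagation from per-variant measurement noise to per-term
# uncertainties, and selection of statistically significant epistatic terms.

#' Propagate per-variant noise into per-term standard deviations
#'
#' Under independent per-variant errors, linear propagation through the
#' epistasis operator gives `sd(term_i) = sqrt(sum_j Omega_ij^2 sd_j^2)`.
#' Both operator forms admit closed forms that avoid materialising `Omega`:
#' background-averaged rows have constant magnitude `(1/2)^(N - order)`, so
#' `sd_i = 2^(order_i - N) * ||noise_sd||_2` (for homoscedastic sd `s` this is
#' the `s * 2^(order - N/2)` law); single-reference rows are +/-1 on the
#' subsets of `i`, so `sd_i = sqrt(sum_{j subset of i} sd_j^2)`.
#'
#' @param n_positions number of positions `N`, or an `epistasis_operator`
#'   (in which case `N` and the form are taken from it and propagation uses
#'   the dense rows — useful for cross-validation).
#' @param noise_sd nonnegative numeric vector of `2^N` per-variant SDs.
#' @param form `"background_averaged"` or `"single_reference"`.
#' @return numeric vector of `2^N` per-term SDs, ascending term index.
#' @export
propagate_noise <- function(n_positions, noise_sd,
                            form = "background_averaged") {
  if (inherits(n_positions, "epistasis_operator")) {
    op <- n_positions
    noise_sd <- .check_noise(noise_sd, op$n_positions)
    return(sqrt(as.numeric(op$omega^2 %*% noise_sd^2)))
  }
  n <- .check_n(n_positions)
  form <- .check_form(form)
  noise_sd <- .check_noise(noise_sd, n)
  o <- term_order(seq_len(2^n) - 1, n)
  if (form == "background_averaged") {
    2^(o - n) * sqrt(sum(noise_sd^2))
  } else {
    sqrt(.zeta(noise_sd^2, n))
  }
}

.check_noise <- function(noise_sd, n_positions) {
  noise_sd <- as.numeric(noise_sd)
  if (length(noise_sd) != 2^n_positions) {
    stop("`noise_sd` must have length 2^N = ", 2^n_positions)
  }
  if (anyNA(noise_sd) || any(noise_sd < 0)) {
    stop("`noise_sd` must be nonnegative")
  }
  noise_sd
}

#' Select statistically significant epistatic terms
#'
#' Computes `z = value/sd` and a two-sided normal-theory p-value per term and
#' flags terms with `p < threshold_p`. No multiple-testing correction is
#' applied by default (raw per-term thresholding); Benjamini-Hochberg
#' adjustment is available via `adjust = "BH"`. The order-0 term (the mean or
#' reference phenotype, not an interaction) is never tested. Terms with
#' `sd = 0` and a nonzero value are flagged trivially significant (`p = 0`).
#'
#' @param spec an [epistasis_spectrum()].
#' @param term_sd per-term SDs from [propagate_noise()].
#' @param threshold_p significance threshold on the (possibly adjusted)
#'   p-value; default 0.01.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a data.frame of class `significance_table` with columns
#'   `term_index`, `order`, `value`, `sd`, `z`, `p`, `selected`, and
#'   attributes `threshold_p`, `n_selected`.
#' @export
significant_terms <- function(spec, term_sd, threshold_p = 0.01,
                              adjust = c("none", "BH")) {
  stopifnot(inherits(spec, "epistasis_spectrum"))
  adjust <- match.arg(adjust)
  n <- spec$n_positions
  term_sd <- as.numeric(term_sd)
  if (length(term_sd) != 2^n) stop("`term_sd` must have length 2^N")
  if (anyNA(term_sd) || any(term_sd < 0)) stop("`term_sd` must be nonnegative")
  if (!is.numeric(threshold_p) || threshold_p <= 0 || threshold_p > 1) {
    stop("`threshold_p` must be in (0, 1]")
  }
  idx <- seq_len(2^n) - 1
  o <- term_order(idx, n)
  value <- spec$terms
  z <- p <- rep(NA_real_, 2^n)
  testable <- idx > 0
  pos_sd <- term_sd > 0
  z[testable & pos_sd] <- value[testable & pos_sd] / term_sd[testable & pos_sd]
  p[testable & pos_sd] <- 2 * stats::pnorm(-abs(z[testable & pos_sd]))
  # degenerate: an exactly-known nonzero term is trivially significant
  zero_sd <- testable & !pos_sd
  p[zero_sd & value != 0] <- 0
  p[zero_sd & value == 0] <- 1
  p_adj <- p
  if (adjust == "BH") {
    p_adj[testable] <- stats::p.adjust(p[testable], method = "BH")
  }
  selected <- !is.na(p_adj) & p_adj < threshold_p & testable
  out <- data.frame(
    term_index = idx, order = o, value = value, sd = term_sd,
    z = z, p = p_adj, selected = selected
  )
  attr(out, "threshold_p") <- threshold_p
  attr(out, "n_selected") <- sum(selected)
  class(out) <- c("significance_table", "data.frame")
  out
}

#' Distribution of selected terms across interaction orders
#'
#' @param table a [significant_terms()] result.
#' @return named integer vector of counts for orders `0..N`; sums to the
#'   number of selected terms.
#' @export
order_distribution <- function(table) {
  stopifnot(inherits(table, "significance_table"))
  n <- max(table$order)
  counts <- integer(n + 1L)
  tab <- table(factor(table$order[table$selected], levels = 0:n))
  counts <- as.integer(tab)
  names(counts) <- 0:n
  counts
}
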