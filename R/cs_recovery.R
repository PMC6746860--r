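# Compressed-sensing estimation of the background-averaged epistatic
# spectrum from a random subsample of phenotypes.
#
# The measurement model is y_obs = A omega with A the sampled rows of
# Omega^-1. Because epistatic spectra are sparse, omega is estimated by
# L1-norm minimisation (basis-pursuit denoising): min ||omega||_1 subject
# to ||A omega - y_obs||_2 <= noise_bound. The L1 step is solved on the
# lasso path (glmnet), taking the least-penalised solution that satisfies
# the residual bound, followed by an optional least-squares refit on the
# selected support; fully determined noiseless systems are solved exactly
# by the transform itself.

#' Draw a random sampling design over the genotype space
#'
#' @param n_positions number of positions `N`.
#' @param fraction fraction of the `2^N` genotypes to sample, in `(0, 1]`.
#'   `round(fraction * 2^N)` indices are drawn uniformly without replacement.
#' @param seed integer seed; the design is reproducible from it.
#' @return object of class `sampling_design`: list with `n_positions`,
#'   `sampled_indices` (0-based, sorted), `fraction` (realised), `seed`.
#' @examples
#' length(sample_design(13, 0.06, seed = 1)$sampled_indices)  # 492
#' @export
sample_design <- function(n_positions, fraction, seed) {
  n <- .check_n(n_positions)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]")
  }
  total <- 2^n
  m <- round(fraction * total)
  if (m < n + 1) {
    warning("design has only ", m, " samples for ", n,
            " positions; recovery is unlikely to be determined")
  }
  m <- max(1L, m)
  set.seed(as.integer(seed))
  sampled <- sort(sample.int(total, m) - 1)
  structure(
    list(n_positions = n, sampled_indices = sampled,
         fraction = m / total, seed = as.integer(seed)),
    class = "sampling_design"
  )
}

# Sampled rows of Omega^-1 (background-averaged):
# (Omega^-1)_{ij} = (-1)^(order(j) + popcount(i & j)) * 2^(-order(j)).
# popcount(i & j) = bits_i . bits_j, so the sign pattern comes from one
# matrix product over the bit representations.
.cs_design_matrix <- function(design) {
  n <- design$n_positions
  all_idx <- seq_len(2^n) - 1
  B_all <- index_to_bits(all_idx, n)
  B_s <- B_all[design$sampled_indices + 1L, , drop = FALSE]
  pc <- B_s %*% t(B_all)
  o <- term_order(all_idx, n)
  sweep((-1)^pc, 2L, (-1)^o * 2^(-o), `*`)
}

#' Estimate the sparse epistatic spectrum from subsampled phenotypes
#'
#' Solves `min ||omega||_1 s.t. ||A omega - y_obs||_2 <= noise_bound` with
#' `A` the sampled rows of the inverse background-averaged operator. The
#' order-0 term — the mean phenotype, not an interaction — corresponds to
#' the constant column of `A` and is excluded from the L1 penalty: it is
#' fitted as an unpenalised intercept. Interaction columns are rescaled to
#' unit norm before the L1 step (their raw norms fall off as `2^(-order)`,
#' which would bias selection by order) and the rescaling is undone on
#' output; set `normalize_columns = FALSE` for the raw weighted basis. By default the solution is debiased by a least-squares
#' refit on the selected support (relaxed lasso). Setting `t_prune` adds a
#' backward-elimination pass over that refit: support terms whose
#' t-statistic falls below the cutoff are dropped and the model refit,
#' repeated to a fixed point — the usual guard against the small spurious
#' coefficients the lasso retains near its residual bound.
#'
#' @param y_obs observed phenotypes on exactly `design$sampled_indices`
#'   (same order), or a full [landscape()] from which they are extracted.
#' @param design a [sample_design()].
#' @param noise_bound residual L2 bound `epsilon >= 0`. `NULL` (default)
#'   selects the penalty by 5-fold cross-validation on the held-in samples;
#'   if per-variant noise SD `s` is known, `s * sqrt(n_sampled)` is the
#'   natural bound.
#' @param normalize_columns rescale design columns to unit norm (default).
#' @param refit least-squares refit on the selected support (default TRUE).
#' @param t_prune optional t-statistic cutoff (e.g. 3) for backward
#'   elimination of support terms after the refit; `NULL` (default)
#'   disables pruning.
#' @param nlambda,lambda_min_ratio lasso path resolution.
#' @return object of class `cs_solution`: list with `spectrum` (an
#'   [epistasis_spectrum()]), `residual_norm`, `solver_status`
#'   (`"optimal"`, `"max_iter"` or `"infeasible"`), `regularization`
#'   (selected lasso penalty), `design`.
#' @export
cs_estimate <- function(y_obs, design, noise_bound = NULL,
                        normalize_columns = TRUE, refit = TRUE,
                        t_prune = NULL, nlambda = 100L,
                        lambda_min_ratio = 1e-6) {
  stopifnot(inherits(design, "sampling_design"))
  n <- design$n_positions
  if (inherits(y_obs, "landscape")) {
    if (y_obs$n_positions != n) stop("landscape/design size mismatch")
    y_obs <- y_obs$phenotypes[design$sampled_indices + 1L]
  }
  y_obs <- as.numeric(y_obs)
  m <- length(design$sampled_indices)
  if (length(y_obs) != m) {
    stop("`y_obs` must hold one value per sampled genotype (", m, ")")
  }

  # fully determined noiseless system: the exact transform is the solution
  if (m == 2^n && (!is.null(noise_bound) && noise_bound == 0)) {
    # sampled_indices is sorted, so y_obs is already in binary order
    spec <- epistasis_transform(landscape(y_obs))
    return(structure(
      list(spectrum = spec, residual_norm = 0, solver_status = "optimal",
           regularization = 0, design = design),
      class = "cs_solution"
    ))
  }

  A_full <- .cs_design_matrix(design)
  A <- A_full[, -1L, drop = FALSE]  # interaction columns; column 1 == 1
  scale_col <- if (normalize_columns) sqrt(colSums(A^2)) else rep(1, ncol(A))
  scale_col[scale_col == 0] <- 1
  As <- sweep(A, 2L, scale_col, `/`)

  fit <- glmnet::glmnet(As, y_obs, family = "gaussian", alpha = 1,
                        intercept = TRUE, standardize = FALSE,
                        nlambda = nlambda, lambda.min.ratio = lambda_min_ratio)
  beta <- as.matrix(fit$beta)
  resid_norm <- sqrt(colSums((As %*% beta +
                                rep(fit$a0, each = m) - y_obs)^2))

  status <- "optimal"
  if (is.null(noise_bound)) {
    cv <- glmnet::cv.glmnet(As, y_obs, family = "gaussian", alpha = 1,
                            intercept = TRUE, standardize = FALSE,
                            nfolds = 5, lambda = fit$lambda)
    pick <- which(fit$lambda == cv$lambda.min)[1]
    if (is.na(pick)) pick <- ncol(beta)
  } else {
    ok <- which(resid_norm <= noise_bound)
    if (length(ok) == 0L) {
      # bound unattainable on the path: report least-residual solution
      pick <- which.min(resid_norm)
      status <- if (m > 2^n) "infeasible" else "max_iter"
    } else {
      pick <- ok[1]  # largest penalty meeting the bound = min-L1 solution
    }
  }
  coef_scaled <- beta[, pick]
  support <- which(coef_scaled != 0)  # indices into interaction columns
  terms <- c(fit$a0[pick], coef_scaled / scale_col)
  if (refit && length(support) > 0 && length(support) + 1L < m) {
    fit_support <- function(supp) {
      ls <- stats::lm.fit(cbind(1, A[, supp, drop = FALSE]), y_obs)
      aliased <- is.na(ls$coefficients[-1])
      if (any(aliased)) {  # drop rank-deficient columns and refit
        supp <- supp[!aliased]
        ls <- stats::lm.fit(cbind(1, A[, supp, drop = FALSE]), y_obs)
      }
      list(ls = ls, support = supp)
    }
    fs <- fit_support(support)
    ls <- fs$ls
    support <- fs$support
    if (!is.null(t_prune)) {
      repeat {
        dof <- m - length(support) - 1L
        if (dof < 1L || length(support) == 0L) break
        s2 <- sum(ls$residuals^2) / dof
        X <- cbind(1, A[, support, drop = FALSE])
        xtx_inv <- tryCatch(chol2inv(chol(crossprod(X))),
                            error = function(e) NULL)
        if (is.null(xtx_inv)) break  # numerically singular: stop pruning
        se <- sqrt(pmax(s2 * diag(xtx_inv), .Machine$double.eps))
        tstat <- abs(ls$coefficients[-1]) / se[-1]  # intercept never pruned
        if (all(tstat >= t_prune)) break
        support <- support[tstat >= t_prune]
        if (length(support) == 0L) break
        fs <- fit_support(support)
        ls <- fs$ls
        support <- fs$support
      }
    }
    terms <- numeric(ncol(A_full))
    if (length(support)) {
      terms[1L] <- ls$coefficients[1]
      terms[support + 1L] <- ls$coefficients[-1]
    } else {
      terms[1L] <- mean(y_obs)
    }
  }
  residual <- sqrt(sum((A_full %*% terms - y_obs)^2))
  structure(
    list(spectrum = epistasis_spectrum(terms, form = "background_averaged"),
         residual_norm = residual, solver_status = status,
         regularization = fit$lambda[pick], design = design),
    class = "cs_solution"
  )
}

#' @export
print.cs_solution <- function(x, ...) {
  cat("CS solution: N =", x$spectrum$n_positions,
      "| sampled", length(x$design$sampled_indices), "genotypes",
      sprintf("(%.1f%%)", 100 * x$design$fraction), "\n")
  cat("  support size:", sum(x$spectrum$terms != 0),
      "| residual:", format(x$residual_norm, digits = 4),
      "| status:", x$solver_status, "\n")
  invisible(x)
}

#' Score phenotype prediction from a CS-estimated spectrum
#'
#' Reconstructs all phenotypes from the estimated spectrum and scores them
#' against the true landscape, on all genotypes or on the held-out
#' (unsampled) ones only.
#'
#' @param sol a [cs_estimate()] solution.
#' @param truth the complete true [landscape()].
#' @param heldout_only score only genotypes outside the sampling design.
#' @return [goodness_of_fit()] metrics.
#' @export
evaluate_prediction <- function(sol, truth, heldout_only = FALSE) {
  stopifnot(inherits(sol, "cs_solution"), inherits(truth, "landscape"))
  n <- truth$n_positions
  if (sol$spectrum$n_positions != n) stop("size mismatch")
  yhat <- reconstruct(sol$spectrum)$phenotypes
  y <- truth$phenotypes
  if (heldout_only) {
    held <- setdiff(seq_len(2^n) - 1, sol$design$sampled_indices)
    y <- y[held + 1L]
    yhat <- yhat[held + 1L]
  }
  goodness_of_fit(y, yhat)
}

#' Support recovery metrics against a known true spectrum
#'
#' @param sol a [cs_estimate()] solution.
#' @param truth_spectrum the true (planted) [epistasis_spectrum()].
#' @param tol absolute magnitude below which an estimated term does not
#'   count as support.
#' @return list with `precision`, `recall`, `true_support`,
#'   `estimated_support` (0-based indices). Order-0 terms are excluded.
#' @export
support_metrics <- function(sol, truth_spectrum, tol = 1e-8) {
  stopifnot(inherits(sol, "cs_solution"),
            inherits(truth_spectrum, "epistasis_spectrum"))
  est <- which(abs(sol$spectrum$terms) > tol) - 1L
  tru <- which(abs(truth_spectrum$terms) > tol) - 1L
  est <- setdiff(est, 0L)
  tru <- setdiff(tru, 0L)
  tp <- length(intersect(est, tru))
  list(
    precision = if (length(est) == 0L) NA_real_ else tp / length(est),
    recall = if (length(tru) == 0L) NA_real_ else tp / length(tru),
    true_support = tru, estimated_support = est
  )
}
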