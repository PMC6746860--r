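# Core epistasis transforms on complete binary genotype spaces.
#
# Background-averaged epistasis is a weighted Walsh-Hadamard transform
# Omega = V H; single-reference ("standard") epistasis is Omega = V X^T H,
# which reduces to the boolean finite-difference (Moebius) transform. Both
# are built from 2x2 block recursions with V0 = H0 = X0 = 1, where the
# recursion step appends the NEW position as the most-significant bit so
# that vectors are in ascending genotype-index ("binary") order.

#' Construct a phenotype landscape over a complete genotype space
#'
#' @param phenotypes numeric vector of length `2^N`, in ascending genotype
#'   index order (index 0 first).
#' @param noise_sd optional nonnegative numeric vector of per-variant
#'   measurement SDs, same length and order.
#' @param stage free-form tag recording the processing stage of the values
#'   (e.g. `"raw"` for pre-linearisation enrichments, `"phenotype"` after).
#' @return an object of class `landscape` with fields `n_positions`,
#'   `phenotypes`, `noise_sd`, `stage`.
#' @export
landscape <- function(phenotypes, noise_sd = NULL, stage = "phenotype") {
  phenotypes <- as.numeric(phenotypes)
  n <- log2(length(phenotypes))
  if (length(phenotypes) < 2L || n != floor(n)) {
    stop("`phenotypes` must have length 2^N for some N >= 1, got ",
         length(phenotypes))
  }
  if (!all(is.finite(phenotypes))) stop("phenotypes must all be finite")
  if (!is.null(noise_sd)) {
    noise_sd <- as.numeric(noise_sd)
    if (length(noise_sd) != length(phenotypes)) {
      stop("`noise_sd` must match `phenotypes` in length")
    }
    if (anyNA(noise_sd) || any(noise_sd < 0)) {
      stop("`noise_sd` must be nonnegative")
    }
  }
  structure(
    list(n_positions = as.integer(n), phenotypes = phenotypes,
         noise_sd = noise_sd, stage = stage),
    class = "landscape"
  )
}

#' @export
print.landscape <- function(x, ...) {
  cat("landscape: N =", x$n_positions, "positions,", length(x$phenotypes),
      "genotypes\n")
  cat("  phenotype range: [", format(min(x$phenotypes), digits = 4), ", ",
      format(max(x$phenotypes), digits = 4), "]\n", sep = "")
  if (!is.null(x$noise_sd)) cat("  per-variant noise SDs attached\n")
  invisible(x)
}

.check_form <- function(form) {
  match.arg(form, c("background_averaged", "single_reference"))
}

#' Build the dense epistasis operator
#'
#' Builds the generator matrices by their 2x2 block recursions
#' (`V_{n+1} = [[V_n/2, 0], [0, -V_n]]`, `H_{n+1} = [[H_n, H_n], [H_n, -H_n]]`,
#' `X_{n+1} = [[X_n, 0], [X_n, X_n]]`) and composes `Omega = V %*% H`
#' (background-averaged) or `Omega = V %*% t(X) %*% H` (single-reference).
#' Dense operators are intended for moderate `N` (validation, small
#' landscapes); [epistasis_transform()] uses O(N 2^N) butterflies and never
#' materialises them.
#'
#' @param n_positions number of biallelic positions `N >= 1`.
#' @param form `"background_averaged"` or `"single_reference"`.
#' @return an object of class `epistasis_operator`: list with `n_positions`,
#'   `form`, `V`, `H`, `X` (single-reference only), `omega`, and the
#'   analytic inverse `omega_inv`.
#' @examples
#' build_operator(1, "background_averaged")$omega  # [[1/2,1/2],[-1,1]]
#' @export
build_operator <- function(n_positions, form = "background_averaged") {
  n_positions <- .check_n(n_positions)
  form <- .check_form(form)
  if (n_positions > 14L) {
    stop("dense operators limited to N <= 14; use epistasis_transform()")
  }
  V <- H <- X <- matrix(1, 1L, 1L)
  for (i in seq_len(n_positions)) {
    zero <- matrix(0, nrow(V), ncol(V))
    V <- rbind(cbind(V / 2, zero), cbind(zero, -V))
    H <- rbind(cbind(H, H), cbind(H, -H))
    X <- rbind(cbind(X, zero), cbind(X, X))
  }
  if (form == "background_averaged") {
    omega <- V %*% H
    # H^-1 = H / 2^N and V is diagonal, so Omega^-1 = H diag(1/V) / 2^N
    omega_inv <- H %*% diag(1 / diag(V), nrow(V)) / 2^n_positions
    X <- NULL
  } else {
    omega <- V %*% t(X) %*% H
    # the single-reference operator is the subset finite-difference
    # transform; its inverse is the subset-sum (zeta) transform X itself
    omega_inv <- X
  }
  structure(
    list(n_positions = n_positions, form = form, V = V, H = H, X = X,
         omega = omega, omega_inv = omega_inv),
    class = "epistasis_operator"
  )
}

#' @export
print.epistasis_operator <- function(x, ...) {
  cat("epistasis operator: N =", x$n_positions, "form =", x$form, "\n")
  invisible(x)
}

# ---- fast butterflies --------------------------------------------------

# In-place style Walsh-Hadamard butterfly: y -> H y, O(N 2^N)
.wht <- function(y, n_positions) {
  len <- length(y)
  h <- 1L
  while (h < len) {
    ix <- seq.int(0L, len - 1L)
    lower <- (ix %% (2L * h)) < h
    a <- ix[lower] + 1L
    b <- a + h
    ya <- y[a]; yb <- y[b]
    y[a] <- ya + yb
    y[b] <- ya - yb
    h <- 2L * h
  }
  y
}

# diagonal of V: V_ii = (-1)^order(i) * (1/2)^(N - order(i))
.v_diag <- function(n_positions) {
  o <- term_order(seq_len(2^n_positions) - 1, n_positions)
  (-1)^o * 0.5^(n_positions - o)
}

# subset finite difference (Moebius) transform: for each bit, b -> b - a
.moebius <- function(y, n_positions) {
  len <- length(y)
  h <- 1L
  while (h < len) {
    ix <- seq.int(0L, len - 1L)
    lower <- (ix %% (2L * h)) < h
    a <- ix[lower] + 1L
    b <- a + h
    y[b] <- y[b] - y[a]
    h <- 2L * h
  }
  y
}

# subset sum (zeta) transform: inverse of .moebius
.zeta <- function(y, n_positions) {
  len <- length(y)
  h <- 1L
  while (h < len) {
    ix <- seq.int(0L, len - 1L)
    lower <- (ix %% (2L * h)) < h
    a <- ix[lower] + 1L
    b <- a + h
    y[b] <- y[b] + y[a]
    h <- 2L * h
  }
  y
}

#' Epistatic spectrum constructor
#'
#' @param terms numeric vector of `2^N` interaction terms, ascending term
#'   index; the order of term `i` is the popcount of `i`.
#' @param form which transform produced the terms.
#' @param reference_index reference genotype (single-reference form only).
#' @return object of class `epistasis_spectrum`.
#' @export
epistasis_spectrum <- function(terms, form = "background_averaged",
                               reference_index = 0) {
  terms <- as.numeric(terms)
  n <- log2(length(terms))
  if (n != floor(n) || length(terms) < 2L) {
    stop("`terms` must have length 2^N")
  }
  form <- .check_form(form)
  structure(
    list(n_positions = as.integer(n), form = form, terms = terms,
         reference_index = if (form == "single_reference") reference_index
                           else NULL),
    class = "epistasis_spectrum"
  )
}

#' @export
print.epistasis_spectrum <- function(x, ...) {
  cat("epistasis spectrum: N =", x$n_positions, "form =", x$form, "\n")
  o <- term_order(seq_along(x$terms) - 1, x$n_positions)
  big <- order(abs(x$terms), decreasing = TRUE)[seq_len(min(5L, length(x$terms)))]
  cat("  largest |terms| at indices:", paste(big - 1L, collapse = ", "), "\n")
  invisible(x)
}

#' Transform a phenotype landscape into epistatic interaction terms
#'
#' Computes `omega = Omega %*% y` where `Omega` is the epistasis operator of
#' the requested form, via O(N 2^N) butterfly passes (identical to the dense
#' route to ~1e-12 relative error). The background-averaged order-0 term is
#' the mean phenotype; the single-reference order-0 term is the reference
#' phenotype. For a non-zero reference the landscape is re-referenced by an
#' XOR relabeling first, so terms are reported relative to that genotype.
#'
#' @param L a [landscape()].
#' @inheritParams build_operator
#' @param reference reference genotype index (single-reference form only).
#' @param method `"fast"` (butterfly) or `"dense"` (explicit operator,
#'   `N <= 14`; mainly for validation).
#' @return an [epistasis_spectrum()].
#' @export
epistasis_transform <- function(L, form = "background_averaged",
                                reference = 0, method = c("fast", "dense")) {
  stopifnot(inherits(L, "landscape"))
  form <- .check_form(form)
  method <- match.arg(method)
  n <- L$n_positions
  y <- L$phenotypes
  if (form == "single_reference" && reference != 0) {
    y <- rereference(L, reference)$phenotypes
  }
  terms <- if (method == "dense") {
    op <- build_operator(n, form)
    as.numeric(op$omega %*% y)
  } else if (form == "background_averaged") {
    .v_diag(n) * .wht(y, n)
  } else {
    .moebius(y, n)
  }
  epistasis_spectrum(terms, form = form, reference_index = reference)
}

#' Alias for the butterfly-based transform
#'
#' @inheritParams epistasis_transform
#' @return an [epistasis_spectrum()].
#' @export
fast_transform <- function(L, form = "background_averaged", reference = 0) {
  epistasis_transform(L, form = form, reference = reference, method = "fast")
}

# inverse transform of a full term vector -> phenotype vector
.inverse_terms <- function(terms, n_positions, form) {
  if (form == "background_averaged") {
    # Omega^-1 = H V^-1 / 2^N
    .wht(terms / .v_diag(n_positions), n_positions) / 2^n_positions
  } else {
    .zeta(terms, n_positions)
  }
}

#' Reconstruct phenotypes from a subset of epistatic terms
#'
#' Computes `yhat = Omega^-1 %*% omega_keep` where `omega_keep` is the
#' spectrum with all terms outside `keep` zeroed. With all terms kept this
#' inverts the transform exactly; with none kept it returns the all-zero
#' landscape.
#'
#' @param spec an [epistasis_spectrum()].
#' @param keep term indices (0-based) to retain; default all.
#' @return a [landscape()] of reconstructed phenotypes (tagged
#'   `stage = "reconstructed"`).
#' @export
reconstruct <- function(spec, keep = NULL) {
  stopifnot(inherits(spec, "epistasis_spectrum"))
  n <- spec$n_positions
  terms <- spec$terms
  if (!is.null(keep)) {
    keep <- .check_index(keep, n)
    if (anyDuplicated(keep)) stop("`keep` must not contain duplicates")
    mask <- rep(FALSE, 2^n)
    mask[keep + 1L] <- TRUE
    terms[!mask] <- 0
  }
  landscape(.inverse_terms(terms, n, spec$form), stage = "reconstructed")
}

#' Goodness of fit and prediction between measured and reconstructed phenotypes
#'
#' `R^2 = 1 - SSE/SST` (negative values possible for reconstructions worse
#' than the mean) and the goodness-of-prediction `GoP = 1/(1 + SSE/SST)`,
#' which maps prediction error into `(0, 1]`.
#'
#' @param y measured [landscape()] or numeric vector.
#' @param yhat reconstructed [landscape()] or numeric vector, same length.
#' @return list of class `fit_metrics` with `sse`, `sst`, `r_squared`, `gop`.
#' @export
goodness_of_fit <- function(y, yhat) {
  if (inherits(y, "landscape")) y <- y$phenotypes
  if (inherits(yhat, "landscape")) yhat <- yhat$phenotypes
  if (length(y) != length(yhat)) stop("`y` and `yhat` differ in length")
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("R^2 undefined: `y` is constant (SST = 0)")
  structure(
    list(sse = sse, sst = sst, r_squared = 1 - sse / sst,
         gop = 1 / (1 + sse / sst)),
    class = "fit_metrics"
  )
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("R^2 = %.4f, GoP = %.4f (SSE = %.4g, SST = %.4g)\n",
              x$r_squared, x$gop, x$sse, x$sst))
  invisible(x)
}

#' Explained-variance contribution of each term
#'
#' For the background-averaged form the columns of `Omega^-1` are mutually
#' orthogonal, so dropping term `i` from a reconstruction adds exactly
#' `c_i = terms[i]^2 * ||col_i(Omega^-1)||^2 = terms[i]^2 * 2^(N - 2 order(i))`
#' to the SSE. Contributions are therefore exactly additive.
#'
#' @inheritParams reconstruct
#' @return numeric vector of contributions `c_i`, ascending term index.
#' @export
term_contributions <- function(spec) {
  stopifnot(inherits(spec, "epistasis_spectrum"))
  if (spec$form != "background_averaged") {
    stop("term contributions are defined for the background-averaged form")
  }
  n <- spec$n_positions
  o <- term_order(seq_len(2^n) - 1, n)
  spec$terms^2 * 2^(n - 2 * o)
}

#' Rank terms by their contribution to explanatory power
#'
#' Orders terms by decreasing explained-variance contribution (see
#' [term_contributions()]); because contributions are exactly additive, the
#' `R^2` of `reconstruct(spec, top_k)` is non-decreasing in `k`. Ties are
#' broken by ascending interaction order then ascending index, for
#' determinism.
#'
#' @inheritParams reconstruct
#' @return numeric vector of 0-based term indices, most explanatory first.
#' @export
rank_terms <- function(spec) {
  ctr <- term_contributions(spec)
  n <- spec$n_positions
  idx <- seq_len(2^n) - 1
  o <- term_order(idx, n)
  idx[order(-ctr, o, idx)]
}

#' Re-reference a landscape by XOR relabeling
#'
#' Permutes phenotypes by `index XOR new_reference`, so that the chosen
#' genotype moves to index 0. The single-reference transform of the result
#' equals epistasis relative to that genotype. The operation is an
#' involution: applying it twice with the same reference is the identity.
#'
#' @param L a [landscape()].
#' @param new_reference genotype index to place at the origin.
#' @return a [landscape()] with permuted phenotypes (and noise SDs).
#' @export
rereference <- function(L, new_reference) {
  stopifnot(inherits(L, "landscape"))
  n <- L$n_positions
  new_reference <- .check_index(new_reference, n)
  idx <- seq_len(2^n) - 1
  perm <- vapply(idx, function(i) .xor_index(i, new_reference, n), numeric(1))
  landscape(L$phenotypes[perm + 1L],
            noise_sd = if (is.null(L$noise_sd)) NULL else L$noise_sd[perm + 1L],
            stage = L$stage)
}
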