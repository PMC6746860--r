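# Conversion of FACS-seq barcode count tables into calibrated brightness
# phenotypes: allelic enrichment, Z-score outlier rejection across
# uniqueness barcodes, channel normalisation, quadratic channel
# combination, removal of global nonlinearity by a power transform, and
# detection-floor pseudocounts.

#' Construct a barcode counts table
#'
#' One row per (allele barcode, uniqueness barcode, channel): input counts
#' are from the unsorted library, output counts from the sorted (gated)
#' population of that color channel.
#'
#' @param allele character vector of allele identifiers (e.g. genotype
#'   binary strings).
#' @param barcode character vector of uniqueness-barcode identifiers.
#' @param channel character vector, `"blue"` or `"red"`.
#' @param n_in,n_out nonnegative integer counts.
#' @return a data.frame of class `counts_table`.
#' @export
counts_table <- function(allele, barcode, channel, n_in, n_out) {
  df <- data.frame(
    allele = as.character(allele), barcode = as.character(barcode),
    channel = as.character(channel), n_in = as.numeric(n_in),
    n_out = as.numeric(n_out), stringsAsFactors = FALSE
  )
  if (!all(df$channel %in% c("blue", "red"))) {
    stop("`channel` must be 'blue' or 'red'")
  }
  if (any(df$n_in < 0) || any(df$n_out < 0) ||
      any(df$n_in != floor(df$n_in)) || any(df$n_out != floor(df$n_out))) {
    stop("counts must be nonnegative integers")
  }
  key <- paste(df$allele, df$barcode, df$channel)
  if (anyDuplicated(key)) {
    stop("(allele, barcode, channel) rows must be unique")
  }
  class(df) <- c("counts_table", "data.frame")
  df
}

#' Outlier-rejection configuration
#'
#' Parameters of the per-barcode Z-score filter: the Poisson-like noise
#' exponent `beta` and the asymmetric acceptance window (reject when
#' `Z > c_upper` or `Z < -c_lower`), applied for `rounds` rounds with
#' enrichment recomputation in between.
#'
#' @param beta noise exponent; default `1/0.35`.
#' @param c_upper,c_lower window bounds; defaults 35 and 15.
#' @param rounds filtering rounds; default 3.
#' @return list of class `outlier_config`.
#' @export
outlier_config <- function(beta = 1 / 0.35, c_upper = 35, c_lower = 15,
                           rounds = 3L) {
  if (beta <= 0 || c_upper <= 0 || c_lower <= 0 || rounds < 1) {
    stop("all outlier-filter parameters must be positive")
  }
  structure(list(beta = beta, c_upper = c_upper, c_lower = c_lower,
                 rounds = as.integer(rounds)),
            class = "outlier_config")
}

#' Linear allelic enrichment from barcode counts
#'
#' Per (allele, channel), the enrichment is the pooled ratio
#' `E_a = sum_k(n_out) / sum_k(n_in)` over retained uniqueness barcodes.
#' (A sum-of-ratios mode `mean_k(n_out/n_in)` is available; the pooled
#' ratio is the default because the downstream Z-score model treats `E_a`
#' as a common rate applied to each barcode's input.) A bootstrap SD over
#' barcodes is attached when an allele has more than one barcode.
#'
#' @param counts a [counts_table()].
#' @param method `"pooled"` (default) or `"sum_of_ratios"`.
#' @param n_boot bootstrap replicates for the per-allele SD (0 disables).
#' @param seed seed for the bootstrap.
#' @return a data.frame of class `enrichment_table` with columns `allele`,
#'   `channel`, `enrichment`, `sd`, `n_barcodes_used`, `n_barcodes_rejected`.
#' @export
allele_enrichment <- function(counts, method = c("pooled", "sum_of_ratios"),
                              n_boot = 200L, seed = 1L) {
  stopifnot(inherits(counts, "counts_table"))
  method <- match.arg(method)
  groups <- split(seq_len(nrow(counts)),
                  paste(counts$allele, counts$channel, sep = "\r"))
  if (n_boot > 0) set.seed(as.integer(seed))
  rows <- lapply(names(groups), function(gname) {
    g <- counts[groups[[gname]], ]
    tot_in <- sum(g$n_in)
    if (tot_in == 0) {
      stop("allele '", g$allele[1], "' channel '", g$channel[1],
           "' has all-zero input counts; enrichment undefined")
    }
    est <- function(rows) {
      if (method == "pooled") sum(rows$n_out) / sum(rows$n_in)
      else mean(rows$n_out[rows$n_in > 0] / rows$n_in[rows$n_in > 0])
    }
    e <- est(g)
    sd_boot <- NA_real_
    if (n_boot > 0 && nrow(g) > 1L) {
      boots <- vapply(seq_len(n_boot), function(b) {
        pick <- sample.int(nrow(g), replace = TRUE)
        gb <- g[pick, ]
        if (sum(gb$n_in) == 0) return(NA_real_)
        est(gb)
      }, numeric(1))
      sd_boot <- stats::sd(boots, na.rm = TRUE)
    }
    data.frame(allele = g$allele[1], channel = g$channel[1],
               enrichment = e, sd = sd_boot,
               n_barcodes_used = nrow(g), n_barcodes_rejected = 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$allele, out$channel), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

# Z score of one barcode given the allele-level enrichment:
# Z = (n_out - E n_in) / (E n_in)^(1/beta)
.barcode_z <- function(n_in, n_out, enrichment, beta) {
  expected <- enrichment * n_in
  ifelse(expected > 0, (n_out - expected) / expected^(1 / beta), NA_real_)
}

#' Iterative Z-score outlier rejection across uniqueness barcodes
#'
#' Per barcode, `Z = (n_out - E_a n_in) / (E_a n_in)^(1/beta)`; a barcode is
#' rejected when `Z > c_upper` or `Z < -c_lower`. Enrichments are recomputed
#' from the retained barcodes and the filter reapplied for `cfg$rounds`
#' rounds. Within a round the upper bound is applied first and enrichments
#' recomputed before the lower bound: a gross over-counting outlier inflates
#' `E_a`, and judging the remaining barcodes against the corrupted rate
#' would cascade into wholesale rejection. A group's last remaining barcode
#' is never rejected. Barcodes whose expected output `E_a n_in` is zero are
#' excluded from the Z computation and logged.
#'
#' @param counts a [counts_table()].
#' @param cfg an [outlier_config()].
#' @param method enrichment estimator passed to [allele_enrichment()].
#' @return list with `counts` (filtered [counts_table()]), `enrichment`
#'   (final `enrichment_table` with rejection tallies), `rejections`
#'   (data.frame log: allele, barcode, channel, round, z, reason).
#' @export
zscore_outlier_filter <- function(counts, cfg = outlier_config(),
                                  method = "pooled") {
  stopifnot(inherits(counts, "counts_table"), inherits(cfg, "outlier_config"))
  keep <- counts
  log_rows <- list()
  pass <- function(keep, round, side) {
    e_tab <- allele_enrichment(keep, method = method, n_boot = 0L)
    key <- paste(keep$allele, keep$channel, sep = "\r")
    ekey <- paste(e_tab$allele, e_tab$channel, sep = "\r")
    e <- e_tab$enrichment[match(key, ekey)]
    z <- .barcode_z(keep$n_in, keep$n_out, e, cfg$beta)
    undefined <- is.na(z)
    reject <- !undefined &
      (if (side == "upper") z > cfg$c_upper else z < -cfg$c_lower)
    # never empty a barcode group
    group_sizes <- stats::ave(seq_along(key), key, FUN = length)
    group_rej <- stats::ave(as.integer(reject), key, FUN = sum)
    reject[reject & group_rej >= group_sizes] <- FALSE
    if (any(undefined) && round == 1L && side == "upper") {
      log_rows[[length(log_rows) + 1L]] <<- data.frame(
        keep[undefined, c("allele", "barcode", "channel")],
        round = round, z = NA_real_, reason = "zero_expected_output"
      )
    }
    if (any(reject)) {
      log_rows[[length(log_rows) + 1L]] <<- data.frame(
        keep[reject, c("allele", "barcode", "channel")],
        round = round, z = z[reject], reason = "z_outlier"
      )
      keep <- keep[!reject, ]
      class(keep) <- c("counts_table", "data.frame")
    }
    list(keep = keep, any = any(reject))
  }
  for (round in seq_len(cfg$rounds)) {
    up <- pass(keep, round, "upper")
    lo <- pass(up$keep, round, "lower")
    keep <- lo$keep
    if (!up$any && !lo$any) break
  }
  rejections <- if (length(log_rows)) do.call(rbind, log_rows)
                else data.frame(allele = character(0), barcode = character(0),
                                channel = character(0), round = integer(0),
                                z = numeric(0), reason = character(0))
  rownames(rejections) <- NULL
  final <- allele_enrichment(keep, method = method)
  n_rej <- table(paste(rejections$allele[rejections$reason == "z_outlier"],
                       rejections$channel[rejections$reason == "z_outlier"],
                       sep = "\r"))
  fkey <- paste(final$allele, final$channel, sep = "\r")
  final$n_barcodes_rejected <- ifelse(fkey %in% names(n_rej),
                                      as.integer(n_rej[fkey]), 0L)
  list(counts = keep, enrichment = final, rejections = rejections)
}

#' Normalise color channels to the parental brightness ratio
#'
#' The red-channel enrichments are rescaled so that the ratio of the red
#' parent's red-channel enrichment to the blue parent's blue-channel
#' enrichment equals the target `r* = (brightness_red / brightness_blue) *
#' red_attenuation` — by default `(25.0e3 / 32.4e3) * 0.222 = 0.772 * 0.222
#' = 0.172`, the published parental brightness ratio attenuated for the
#' off-peak red assay wavelengths. Rescaling is a single positive factor per
#' channel, so within-channel rank order is unchanged.
#'
#' @param E an `enrichment_table` containing both parental alleles.
#' @param blue_parent,red_parent allele identifiers of the parents.
#' @param brightness_red,brightness_blue parental molecular brightnesses
#'   (defaults 25.0e3 and 32.4e3).
#' @param red_attenuation apparent-red attenuation factor (default 0.222).
#' @return the `enrichment_table` with red-channel enrichments rescaled;
#'   attributes `target_ratio` and `scale_factor` record the calibration.
#' @export
normalize_channels <- function(E, blue_parent, red_parent,
                               brightness_red = 25.0e3,
                               brightness_blue = 32.4e3,
                               red_attenuation = 0.222) {
  stopifnot(inherits(E, "enrichment_table"))
  target <- (brightness_red / brightness_blue) * red_attenuation
  e_blue <- E$enrichment[E$allele == blue_parent & E$channel == "blue"]
  e_red <- E$enrichment[E$allele == red_parent & E$channel == "red"]
  if (length(e_blue) != 1L || length(e_red) != 1L) {
    stop("both parental alleles must be present in their own channels")
  }
  if (e_red == 0) stop("red parent has zero red-channel enrichment")
  scale <- target * e_blue / e_red
  red_rows <- E$channel == "red"
  E$enrichment[red_rows] <- E$enrichment[red_rows] * scale
  E$sd[red_rows] <- E$sd[red_rows] * scale
  attr(E, "target_ratio") <- target
  attr(E, "scale_factor") <- scale
  E
}

#' Quadratic combination of the two color channels
#'
#' `x = sqrt(E_blue^2 + E_red^2)`: symmetric, homogeneous of degree one, and
#' never less than either channel alone.
#'
#' @param e_blue,e_red nonnegative enrichments (vectorised).
#' @return combined brightness values.
#' @examples
#' combine_channels(3, 4)  # 5
#' @export
combine_channels <- function(e_blue, e_red) {
  if (any(e_blue < 0) || any(e_red < 0)) {
    stop("channel enrichments must be nonnegative")
  }
  sqrt(e_blue^2 + e_red^2)
}

#' Fit a power transform removing global nonlinearity
#'
#' Finds the exponent `alpha` such that `y = x^alpha` is maximally
#' representable by epistatic terms up to `max_order`: minimises
#' `||f(x) - Omega^-1 S Omega f(x)||^2 / var(f(x))` with `f(x) = x^alpha`
#' and `S` the order-<=`max_order` selector, by golden-section search to
#' tolerance 1e-4. Global (measurement-process) nonlinearities curve every
#' variant alike, while true epistasis is variant-specific; maximising low-order
#' representability removes the former without modelling it mechanistically.
#'
#' @param x a [landscape()] of nonnegative raw combined enrichments.
#' @param max_order interaction order retained by the selector (default 2).
#' @param alpha_bounds search interval for `alpha` (default `c(0.05, 2)`).
#' @return list of class `power_transform`: `alpha`, `objective_value`,
#'   `transformed` (the [landscape()] `y = x^alpha`), `boundary` (TRUE if
#'   the optimum sits at a search bound).
#' @export
fit_power_transform <- function(x, max_order = 2L,
                                alpha_bounds = c(0.05, 2.0)) {
  stopifnot(inherits(x, "landscape"))
  vals <- x$phenotypes
  if (any(vals < 0)) stop("power transform requires nonnegative values")
  if (all(vals == 0)) stop("all-zero landscape; power transform undefined")
  n <- x$n_positions
  o <- term_order(seq_len(2^n) - 1, n)
  low <- o <= max_order
  objective <- function(alpha) {
    y <- vals^alpha
    if (stats::var(y) == 0) return(Inf)
    w <- .v_diag(n) * .wht(y, n)
    w[!low] <- 0
    yhat <- .inverse_terms(w, n, "background_averaged")
    sum((y - yhat)^2) / sum((y - mean(y))^2)
  }
  opt <- stats::optimize(objective, interval = alpha_bounds, tol = 1e-4)
  boundary <- min(opt$minimum - alpha_bounds[1],
                  alpha_bounds[2] - opt$minimum) < 1e-3
  if (boundary) {
    warning("power-transform optimum at search boundary (alpha = ",
            format(opt$minimum, digits = 4), ")")
  }
  structure(
    list(alpha = opt$minimum, objective_value = opt$objective,
         transformed = landscape(vals^opt$minimum, noise_sd = x$noise_sd,
                                 stage = "phenotype"),
         boundary = boundary),
    class = "power_transform"
  )
}

#' @export
print.power_transform <- function(x, ...) {
  cat(sprintf("power transform: alpha = %.4f (objective %.4g)\n",
              x$alpha, x$objective_value))
  invisible(x)
}

#' Clamp phenotypes below the detection floor
#'
#' Values below the assay's detection floor carry no information beyond
#' "not detected"; they are deterministically clamped to the floor
#' (monotone: no value ever decreases, and values both above the floor keep
#' their order).
#'
#' @param y a [landscape()].
#' @param detection_floor nonnegative floor value.
#' @return the clamped [landscape()].
#' @export
apply_pseudocounts <- function(y, detection_floor) {
  stopifnot(inherits(y, "landscape"))
  if (detection_floor < 0) stop("`detection_floor` must be >= 0")
  landscape(pmax(y$phenotypes, detection_floor), noise_sd = y$noise_sd,
            stage = y$stage)
}

#' Estimate the detection floor from null-class genotypes
#'
#' The floor is the 95th percentile of values among genotypes flagged as
#' consistent with zero brightness (the null class), a deterministic
#' summary of the fitting noise present in non-functional genotypes.
#'
#' @param y a [landscape()].
#' @param null_mask logical vector marking null-class genotypes.
#' @param probs percentile (default 0.95).
#' @return the floor value.
#' @export
estimate_detection_floor <- function(y, null_mask, probs = 0.95) {
  stopifnot(inherits(y, "landscape"), is.logical(null_mask),
            length(null_mask) == length(y$phenotypes))
  if (!any(null_mask)) return(0)
  as.numeric(stats::quantile(y$phenotypes[null_mask], probs = probs))
}

#' Validate a segment barcode's parity base
#'
#' Segment barcodes are three bases plus a parity base equal to the numeric
#' sum of the three bases modulo four, which detects any single-base error.
#'
#' @param code 4-character string over `{A, C, G, T}`.
#' @param base_map named integer mapping of bases to 0..3 (default
#'   alphabetical: A=0, C=1, G=2, T=3).
#' @return TRUE iff the parity base checks out.
#' @examples
#' validate_segment_barcode("ACGT")  # TRUE: (0 + 1 + 2) %% 4 = 3 = T
#' @export
validate_segment_barcode <- function(code,
                                     base_map = c(A = 0, C = 1, G = 2, T = 3)) {
  if (nchar(code) != 4L) stop("segment barcode must have exactly 4 bases")
  chars <- strsplit(code, "", fixed = TRUE)[[1]]
  if (!all(chars %in% names(base_map))) {
    stop("segment barcode contains a non-ACGT character: ", code)
  }
  vals <- base_map[chars]
  unname(vals[4] == sum(vals[1:3]) %% 4)
}

#' Preprocess barcode counts into a calibrated phenotype landscape
#'
#' Runs the full chain: outlier-filtered enrichment per channel, channel
#' normalisation to the parental brightness ratio, quadratic combination,
#' power-transform linearisation, and detection-floor pseudocounts. Allele
#' identifiers must be genotype binary strings covering the complete space.
#'
#' @param counts a [counts_table()] with both channels.
#' @param n_positions number of positions `N`.
#' @param cfg an [outlier_config()].
#' @param blue_parent,red_parent parental genotype strings; defaults are the
#'   all-zeros and all-ones strings.
#' @param detection_floor floor passed to [apply_pseudocounts()]; `NULL`
#'   skips clamping.
#' @param fit_alpha fit the power transform (default TRUE; otherwise
#'   `y = x`).
#' @param ... further arguments to [normalize_channels()].
#' @return list with `landscape` (final [landscape()], noise SDs from the
#'   barcode bootstrap), `raw` (pre-transform combined [landscape()]),
#'   `enrichment`, `rejections`, `power` (the [fit_power_transform()] result
#'   or NULL).
#' @export
preprocess_counts <- function(counts, n_positions, cfg = outlier_config(),
                              blue_parent = NULL, red_parent = NULL,
                              detection_floor = NULL, fit_alpha = TRUE, ...) {
  n <- .check_n(n_positions)
  if (is.null(blue_parent)) blue_parent <- strrep("0", n)
  if (is.null(red_parent)) red_parent <- strrep("1", n)
  filt <- zscore_outlier_filter(counts, cfg)
  E <- normalize_channels(filt$enrichment, blue_parent, red_parent, ...)
  genotypes <- format_genotype(seq_len(2^n) - 1, n)
  pick <- function(channel) {
    rows <- E[E$channel == channel, ]
    m <- match(genotypes, rows$allele)
    if (anyNA(m)) {
      stop("missing ", channel, "-channel enrichment for genotypes: ",
           paste(utils::head(genotypes[is.na(m)], 5L), collapse = ", "))
    }
    rows[m, ]
  }
  blue <- pick("blue")
  red <- pick("red")
  x <- combine_channels(blue$enrichment, red$enrichment)
  # propagate bootstrap SDs through the quadratic combination
  sd_x <- ifelse(x > 0,
                 sqrt((blue$enrichment * ifelse(is.na(blue$sd), 0, blue$sd))^2 +
                      (red$enrichment * ifelse(is.na(red$sd), 0, red$sd))^2) / x,
                 0)
  raw <- landscape(x, noise_sd = sd_x, stage = "raw")
  power <- NULL
  y <- raw
  if (fit_alpha) {
    power <- fit_power_transform(raw)
    # delta method: sd(x^alpha) = alpha x^(alpha-1) sd(x)
    a <- power$alpha
    sd_y <- ifelse(x > 0, a * x^(a - 1) * sd_x, 0)
    y <- landscape(power$transformed$phenotypes, noise_sd = sd_y,
                   stage = "phenotype")
  }
  if (!is.null(detection_floor)) y <- apply_pseudocounts(y, detection_floor)
  list(landscape = y, raw = raw, enrichment = E,
       rejections = filt$rejections, power = power)
}
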