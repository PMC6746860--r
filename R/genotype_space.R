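# Maximum number of biallelic positions for full-space enumeration. 2^24
# phenotype vectors are the largest this package will materialise.
.MAX_POSITIONS <- 24L

#' Convert a binary allele vector to a genotype index
#'
#' Genotypes over `N` biallelic positions are indexed by the integer whose
#' bit `k` (least-significant bit = bit 0) encodes the allele at position
#' `k + 1`. Bit value 0 is the first parental allele (here: the blue parent,
#' mTagBFP2), bit value 1 the second (red parent, mKate2), so the blue parent
#' is index 0 and the red parent index `2^N - 1`.
#'
#' @param bits integer (or logical) vector of 0/1 alleles, position 1 first.
#' @return a single numeric index in `[0, 2^N)`.
#' @examples
#' genotype_index(c(1, 0, 0))  # 1
#' genotype_index(rep(1, 13))  # 8191
#' @export
genotype_index <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) < 1L) stop("`bits` must have length >= 1")
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("`bits` must contain only 0 and 1")
  }
  sum(bits * 2^(seq_along(bits) - 1L))
}

#' Convert a genotype index back to its allele vector
#'
#' Inverse of [genotype_index()].
#'
#' @param index genotype index (vectorised), in `[0, 2^N)`.
#' @param n_positions number of positions `N`.
#' @return if `index` has length 1, an integer vector of length `N`;
#'   otherwise a `length(index) x N` integer matrix with one genotype per row.
#' @export
index_to_bits <- function(index, n_positions) {
  n_positions <- .check_n(n_positions)
  index <- .check_index(index, n_positions)
  b <- vapply(seq_len(n_positions) - 1L,
              function(k) as.integer(index %/% 2^k %% 2),
              integer(length(index)))
  if (length(index) == 1L) as.integer(b) else matrix(b, nrow = length(index))
}

#' Number of positions participating in a term or genotype (popcount)
#'
#' The interaction order of a term in an epistatic spectrum, or the mutational
#' (Hamming) layer of a genotype, is the number of set bits of its index.
#'
#' @inheritParams index_to_bits
#' @return integer vector of popcounts.
#' @export
term_order <- function(index, n_positions) {
  n_positions <- .check_n(n_positions)
  index <- .check_index(index, n_positions)
  out <- integer(length(index))
  for (k in seq_len(n_positions) - 1L) {
    out <- out + as.integer(index %/% 2^k %% 2)
  }
  out
}

#' Single-mutation neighbors of a genotype
#'
#' The `N` genotypes at Hamming distance one: the index with each bit
#' flipped in turn.
#'
#' @param index a single genotype index.
#' @inheritParams index_to_bits
#' @return numeric vector of `N` neighbor indices.
#' @export
hamming_neighbors <- function(index, n_positions) {
  n_positions <- .check_n(n_positions)
  index <- .check_index(index, n_positions)
  if (length(index) != 1L) stop("`index` must be a single genotype")
  vapply(seq_len(n_positions) - 1L, function(k) .xor_bit(index, k), numeric(1))
}

# index XOR 2^k without 32-bit overflow (indices can exceed .Machine$integer.max
# territory only for n > 24, which is capped, but keep arithmetic in doubles)
.xor_bit <- function(index, k) {
  bit <- index %/% 2^k %% 2
  index + (1 - 2 * bit) * 2^k
}

# XOR of two genotype indices, bitwise, in double arithmetic
.xor_index <- function(a, b, n_positions) {
  out <- 0
  for (k in seq_len(n_positions) - 1L) {
    ba <- a %/% 2^k %% 2
    bb <- b %/% 2^k %% 2
    out <- out + ((ba + bb) %% 2) * 2^k
  }
  out
}

#' Enumerate the complete genotype space
#'
#' All `2^N` genotypes in ascending index order ("binary order"), the order in
#' which phenotype and spectrum vectors are stored throughout the package.
#'
#' @inheritParams index_to_bits
#' @param position_map optional [position_map()] used to label genotypes.
#' @return a data.frame with columns `index`, `genotype` (binary string,
#'   leftmost character = position 1) and `order` (mutational layer).
#' @examples
#' nrow(enumerate_space(3))   # 8
#' @export
enumerate_space <- function(n_positions, position_map = NULL) {
  n_positions <- .check_n(n_positions)
  idx <- seq_len(2^n_positions) - 1
  bits <- index_to_bits(idx, n_positions)
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1L)
  df <- data.frame(
    index = idx,
    genotype = apply(bits, 1L, paste0, collapse = ""),
    order = term_order(idx, n_positions),
    stringsAsFactors = FALSE
  )
  if (!is.null(position_map)) {
    stopifnot(inherits(position_map, "position_map"))
    df$label <- vapply(seq_along(idx), function(i) {
      on <- bits[i, ] == 1L
      if (!any(on)) position_map$reference_label
      else paste(position_map$names[on], collapse = "/")
    }, character(1))
  }
  df
}

#' Position labels for a genotype space
#'
#' Associates each bit with a mutation label (e.g. `"V45A"`) and each allele
#' state with a parental name, as in a blue/red fluorescent-protein cross
#' where bit 0 carries the blue-parent residue and bit 1 the red-parent one.
#'
#' @param names character vector of `N` unique position labels, position 1
#'   first (= least-significant bit).
#' @param allele0_label,allele1_label names for the two parental states.
#' @param reference_label label to use for the all-zeros genotype.
#' @return an object of class `position_map`.
#' @export
position_map <- function(names, allele0_label = "allele0",
                         allele1_label = "allele1",
                         reference_label = "reference") {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("position names must be unique")
  structure(
    list(names = names, n_positions = length(names),
         allele0_label = allele0_label, allele1_label = allele1_label,
         reference_label = reference_label),
    class = "position_map"
  )
}

#' Parse a genotype string
#'
#' @param genotype length-N string over `{0,1}`, leftmost character =
#'   position 1.
#' @return numeric genotype index.
#' @export
parse_genotype <- function(genotype) {
  chars <- strsplit(genotype, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("0", "1"))) {
    stop("genotype string must contain only '0' and '1': ", genotype)
  }
  genotype_index(as.integer(chars))
}

#' Format a genotype index as a binary string
#'
#' @inheritParams hamming_neighbors
#' @return character string, leftmost character = position 1.
#' @export
format_genotype <- function(index, n_positions) {
  n_positions <- .check_n(n_positions)
  index <- .check_index(index, n_positions)
  bits <- index_to_bits(index, n_positions)
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = length(index))
  apply(bits, 1L, paste0, collapse = "")
}

.check_n <- function(n_positions) {
  n_positions <- as.integer(n_positions)
  if (length(n_positions) != 1L || is.na(n_positions) || n_positions < 1L) {
    stop("`n_positions` must be a single integer >= 1")
  }
  if (n_positions > .MAX_POSITIONS) {
    stop("`n_positions` = ", n_positions, " exceeds the supported maximum of ",
         .MAX_POSITIONS)
  }
  n_positions
}

.check_index <- function(index, n_positions) {
  index <- as.numeric(index)
  if (anyNA(index) || any(index < 0) || any(index >= 2^n_positions) ||
      any(index != floor(index))) {
    stop("genotype indices must be integers in [0, 2^N)")
  }
  index
}
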