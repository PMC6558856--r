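#' Physicochemical property scales of the 20 essential amino acids
#'
#' The 20 x 14 table of amino-acid property-scale values used to translate
#' sequences into numeric profiles: two hydrophobicity scales (H11, H12),
#' hydrophilicity (H2), net charge index of the side chains (NCI), two
#' polarity scales (P11, P12), polarizability (P2), solvent-accessible
#' surface area (SASA), side-chain volume (V), flexibility (F),
#' accessibility (A1), exposed fraction (E), turns scale (T) and antigenic
#' propensity (A2). Shipped as a plain TSV under `inst/extdata` so the
#' encoding is bit-reproducible.
#'
#' @return A tibble with column `aa` (one-letter code) and the 14 scale
#'   columns, rows ordered alphabetically by amino acid.
#' @export
#' @examples
#' physchem_scales()
physchem_scales <- function() {
  if (is.null(the$scales)) {
    path <- system.file("extdata", "physchem_scales.tsv", package = "ppistack",
                        mustWork = TRUE)
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    stopifnot(nrow(tbl) == 20L, ncol(tbl) == 15L, !anyNA(tbl))
    the$scales <- tbl
  }
  the$scales
}

# package-local cache
the <- new.env(parent = emptyenv())

#' Canonical order of the 14 property scales
#' @return Character vector of scale identifiers.
#' @export
scale_names <- function() {
  setdiff(names(physchem_scales()), "aa")
}

#' Sanitize an amino-acid sequence
#'
#' Uppercases the sequence and applies the nonstandard-residue policy for
#' symbols outside the 20 essentials (B, Z, X, U, O, `*`, gaps, ...).
#'
#' @param sequence Character scalar.
#' @param nonstandard `"drop"` removes offending residues with a warning;
#'   `"error"` rejects the sequence, naming the first offending symbol and
#'   its position.
#' @return Sanitized sequence (character scalar).
#' @export
sanitize_sequence <- function(sequence, nonstandard = c("drop", "error")) {
  nonstandard <- match.arg(nonstandard)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq_up <- toupper(gsub("[[:space:]]", "", sequence))
  chars <- strsplit(seq_up, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% physchem_scales()$aa)
  if (any(bad)) {
    if (nonstandard == "error") {
      i <- which(bad)[1]
      abort(sprintf("non-standard residue '%s' at position %d", chars[i], i))
    }
    warn(sprintf("dropped %d non-standard residue(s): %s",
                 sum(bad), paste(unique(chars[bad]), collapse = ", ")))
    chars <- chars[!bad]
  }
  paste(chars, collapse = "")
}

#' Translate a sequence into per-residue property-scale values
#'
#' @param sequence Amino-acid string (sanitized with [sanitize_sequence()]
#'   first).
#' @param scales Scale table, defaults to [physchem_scales()].
#' @inheritParams sanitize_sequence
#' @return Tibble with one row per residue: `position`, `residue` and the
#'   14 scale columns in canonical order.
#' @export
#' @examples
#' translate_sequence("ACDY")
translate_sequence <- function(sequence, scales = physchem_scales(),
                               nonstandard = c("drop", "error")) {
  seq_clean <- sanitize_sequence(sequence, nonstandard)
  if (nchar(seq_clean) == 0L) abort("sequence is empty after sanitization")
  chars <- strsplit(seq_clean, "", fixed = TRUE)[[1]]
  idx <- match(chars, scales$aa)
  bind_cols(
    tibble(position = seq_along(chars), residue = chars),
    scales[idx, setdiff(names(scales), "aa")]
  )
}

#' Lagged auto-covariance of a numeric profile
#'
#' `AC_g = (1/(L-g)) * sum_{j=1}^{L-g} (x_j - mean(x)) * (x_{j+g} - mean(x))`,
#' the average co-deviation of residues separated by `gap` positions. For
#' `gap >= length(x)` the empty sum yields 0, so short proteins still encode
#' to full-length vectors.
#'
#' @param x Numeric vector (one property scale along the sequence).
#' @param gap Positive integer lag.
#' @return A single numeric value.
#' @export
#' @examples
#' auto_covariance(c(0, 2, 0, 2), 1) # -1
auto_covariance <- function(x, gap) {
  stopifnot(is.numeric(x), length(gap) == 1L, gap >= 1)
  L <- length(x)
  if (gap >= L) return(0)
  mu <- mean(x)
  d <- x - mu
  sum(d[1:(L - gap)] * d[(1 + gap):L]) / (L - gap)
}

ac_feature_names <- function(max_gap, scales = scale_names()) {
  # scale-major then gap: scale1 g1, scale1 g2, ...
  unlist(lapply(scales, function(s) paste0("ac_", s, "_g", seq_len(max_gap))))
}

encode_one_protein <- function(sequence, max_gap, scales,
                               nonstandard = "drop") {
  prof <- translate_sequence(sequence, scales, nonstandard)
  cols <- setdiff(names(scales), "aa")
  out <- numeric(length(cols) * max_gap)
  k <- 0L
  for (s in cols) {
    x <- prof[[s]]
    for (g in seq_len(max_gap)) {
      k <- k + 1L
      out[k] <- auto_covariance(x, g)
    }
  }
  names(out) <- ac_feature_names(max_gap, cols)
  out
}

#' Encode proteins as fixed-length auto-covariance vectors
#'
#' Every protein, regardless of length, is represented by `14 * max_gap`
#' auto-covariance values (scale-major, then gap), so variable-length
#' sequences become a uniform input for the classifiers.
#'
#' @param proteins Data frame with columns `protein_id` and `sequence`.
#' @param max_gap Maximum gap G; the vector length is `14 * max_gap`. Capped
#'   at the shortest sanitized sequence length minus one (with a warning) so
#'   no protein's profile is shorter than the largest lag.
#' @inheritParams translate_sequence
#' @return Tibble: `protein_id` plus `14 * max_gap` `ac_*` columns.
#' @export
#' @examples
#' encode_proteins(tibble::tibble(protein_id = c("a", "b"),
#'                                sequence = c("ACDEF", "WYV")),
#'                 max_gap = 2)
encode_proteins <- function(proteins, max_gap = 30,
                            scales = physchem_scales(),
                            nonstandard = c("drop", "error")) {
  nonstandard <- match.arg(nonstandard)
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  if (max_gap < 1) abort("max_gap must be >= 1")
  lens <- vapply(proteins$sequence, function(s) {
    nchar(suppressWarnings(sanitize_sequence(s, "drop")))
  }, integer(1))
  if (any(lens == 0L)) {
    abort(sprintf("empty sequence for protein '%s'",
                  proteins$protein_id[which(lens == 0L)[1]]))
  }
  cap <- min(lens) - 1L
  if (max_gap > cap) {
    warn(sprintf("max_gap %d exceeds shortest sequence; capped at %d",
                 max_gap, cap))
    max_gap <- cap
  }
  vecs <- lapply(proteins$sequence, encode_one_protein,
                 max_gap = max_gap, scales = scales,
                 nonstandard = nonstandard)
  bind_cols(tibble(protein_id = proteins$protein_id),
            as_tibble(do.call(rbind, vecs)))
}

#' Fit the two-stage feature normalizer
#'
#' Standardizes each feature to zero mean and unit standard deviation, then
#' min-max rescales the standardized values to `[0, 1]` (fit on training data
#' only). Zero-variance features use SD = 1 (becoming centered constants);
#' zero-range features map to 0.
#'
#' @param x Numeric matrix or data frame of training feature rows.
#' @return A `ppi_normalizer` object.
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) abort("need at least 2 training rows to fit a normalizer")
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  s <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  structure(
    list(mean = mu, sd = sdv,
         min = apply(s, 2, min), max = apply(s, 2, max)),
    class = "ppi_normalizer"
  )
}

#' Apply a fitted normalizer
#'
#' Values falling outside the training min-max range (possible at test time)
#' are clipped to `[0, 1]`, suppressing outliers.
#'
#' @param stats A `ppi_normalizer` from [fit_normalizer()].
#' @param x Numeric matrix or data frame with the same columns.
#' @return Numeric matrix of values in `[0, 1]`.
#' @export
apply_normalizer <- function(stats, x) {
  stopifnot(inherits(stats, "ppi_normalizer"))
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(stats$mean))
  s <- sweep(sweep(x, 2, stats$mean), 2, stats$sd, "/")
  rng <- stats$max - stats$min
  v <- sweep(s, 2, stats$min)
  v <- sweep(v, 2, ifelse(rng == 0, 1, rng), "/")
  v[, rng == 0] <- 0
  pmin(pmax(v, 0), 1)
}

#' Both concatenation orders of a protein pair's feature vectors
#'
#' A pair (P1, P2) is represented by both `[v1, v2]` and `[v2, v1]`; training
#' uses both orderings as separate instances with the same label, and
#' prediction averages over the two orders.
#'
#' @param v1,v2 Equal-length numeric vectors.
#' @return List with elements `o12` and `o21`, each of length
#'   `2 * length(v1)`.
#' @export
pair_vectors <- function(v1, v2) {
  if (length(v1) != length(v2)) abort("pair vectors must have equal length")
  list(o12 = c(v1, v2), o21 = c(v2, v1))
}
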