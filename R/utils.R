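# Internal validators and small shared helpers.

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  if (integerish && x != round(x)) {
    abort(sprintf("`%s` must be a whole number, got %s.", name, format(x)))
  }
  invisible(x)
}

check_proportion <- function(x, name) {
  check_scalar_number(x, name)
  if (x <= 0 || x >= 1) {
    abort(sprintf("`%s` must lie strictly in (0, 1), got %s.", name, format(x)))
  }
  invisible(x)
}

check_columns <- function(x, cols, name = deparse(substitute(x))) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0L) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  name, paste(missing, collapse = ", ")))
  }
  invisible(x)
}

#' Derive a substream seed from a master seed
#'
#' Deterministic hash of a master seed and one or more stream indices,
#' always below 2^31 - 1 so it is a valid R integer seed.  Used throughout
#' the simulator so that one master seed reproducibly expands into
#' per-library, per-replicate substreams.
#'
#' @param master Master integer seed.
#' @param ... Integer stream indices.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, 5, 2)
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (i in idx) {
    h <- (h * 48271 + as.double(i) * 16807 + 1) %% 2147483647
  }
  as.integer(h)
}

variant_label <- function(ref_aa, residue_index, alt_aa) {
  ifelse(is.na(residue_index), alt_aa,
         paste0(ref_aa, residue_index, alt_aa))
}

reverse_string <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

reverse_complement <- function(x) {
  reverse_string(chartr("ACGTN", "TGCAN", x))
}
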