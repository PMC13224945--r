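#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; summary tables here follow the
#' commercial "half-up" convention so that printed percentages recompute
#' exactly from their counts (e.g. 10/64 = 15.625 -> 15.63).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(15.625, 2) # 15.63, where round() gives 15.62
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Normalise an AOP-Wiki event identifier
#'
#' AOP-Wiki exports (and the literature citing them) print the same event id
#' both as `"KE1964"` and `"KE 1964"`. Internal whitespace is stripped so the
#' two forms compare equal.
#'
#' @param x character vector of event ids.
#' @return character vector with all whitespace removed.
#' @export
normalise_event_id <- function(x) {
  gsub("\\s+", "", as.character(x))
}

# Blank-ish strings ("", "NA", "N/A", actual NA) collapse to the sentinel "NA"
# before any recoding; everything else is returned trimmed.
blank_to_na_label <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | !nzchar(x) | toupper(x) %in% c("NA", "N/A")] <- "NA"
  x
}

# percentage at a given printed precision (half-up); NULL-safe for empty N
pct_of <- function(n, total, digits = 2) {
  if (!length(total) || total == 0) return(rep(NA_real_, length(n)))
  round_half_up(100 * n / total, digits)
}

assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single non-negative integer.", name))
  }
  invisible(as.integer(x))
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(as.numeric(x))
}

# rebuild a tibble from its columns only, shedding carried-over attributes
# (e.g. the audit attributes a roster accumulates during harmonisation)
strip_table_attrs <- function(df) {
  tibble::as_tibble(setNames(lapply(names(df), function(n) df[[n]]), names(df)))
}

# run `expr` under a fixed RNG state and restore whatever was there before
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}
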