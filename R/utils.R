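# Shared helpers: reproducible RNG scoping and exact threshold grids.

# Run `expr` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Build an exact score-threshold grid
#'
#' Grids are generated by integer steps and divided down so that values
#' such as 0.65 and 1.0 are exactly representable and inclusive endpoints
#' never drift by floating-point accumulation. The two standard grids are
#' 0.25 to 0.95 by 0.10 (empty-image filtering, richness) and 0.25 to 1.0
#' by 0.05 (species classification).
#'
#' @param start,stop,step grid bounds and increment, all multiples of
#'   1/100 within \[0,1\].
#' @return numeric vector of thresholds, strictly increasing, endpoints
#'   inclusive.
#' @examples
#' threshold_grid(0.25, 0.95, 0.10)
#' threshold_grid(0.25, 1.00, 0.05)
#' @export
threshold_grid <- function(start = 0.25, stop = 1.0, step = 0.05) {
  s0 <- round(start * 100)
  s1 <- round(stop * 100)
  st <- round(step * 100)
  if (abs(start * 100 - s0) > 1e-9 || abs(stop * 100 - s1) > 1e-9 ||
      abs(step * 100 - st) > 1e-9) {
    stop("grid bounds and step must be multiples of 0.01")
  }
  if (st <= 0 || s1 < s0 || s0 < 0 || s1 > 100) {
    stop("invalid grid: need 0 <= start <= stop <= 1 and step > 0")
  }
  seq.int(s0, s1, by = st) / 100
}

#' Parse a "start:stop:step" grid specification
#' @param spec a string such as `"0.25:0.95:0.10"`.
#' @return numeric threshold grid (see [threshold_grid()]).
#' @export
parse_grid_spec <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L) stop("grid spec must be start:stop:step, got ", spec)
  vals <- suppressWarnings(as.numeric(parts))
  if (any(is.na(vals))) stop("non-numeric grid spec: ", spec)
  threshold_grid(vals[[1]], vals[[2]], vals[[3]])
}

check_threshold_grid <- function(thresholds) {
  if (length(thresholds) == 0L) stop("empty threshold grid")
  if (any(thresholds < 0 | thresholds > 1)) {
    stop("thresholds must lie in [0,1]")
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  invisible(thresholds)
}
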