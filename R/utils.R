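# Arithmetic helpers shared by the blood-lead scenario emulation and report
# formatting. Both guard against binary floating point landing an exact
# decimal a hair below its integer image (e.g. 13770 stored as 13769.999...).

#' Round half away from zero at a fixed number of decimals
#'
#' Commercial ("half-up") rounding, as spreadsheets apply it, rather than
#' base R's round-half-to-even. Used by the blood-lead table emulation mode.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.00345144, 4) # 0.0035
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(round(abs(x) * scale, 7) + 0.5) / scale
}

#' Truncate toward zero at a fixed number of decimals
#'
#' Drops all decimals beyond `digits` without rounding, the scheme under
#' which the published mother-to-fetus blood-lead cells were produced.
#'
#' @inheritParams round_half_up
#' @return `x` truncated toward zero at `digits` decimals.
#' @export
#' @examples
#' trunc_to(1.728475, 4) # 1.7284, not 1.7285
trunc_to <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(round(abs(x) * scale, 7)) / scale
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards. NULL seed = use the current
# stream (and advance it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  expr
}

stop_liprisk <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "liprisk_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_scalar_number <- function(x, name, lower = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_liprisk(sprintf("`%s` must be a single non-missing number", name),
                 "liprisk_parameter_error")
  }
  if (x < lower || (!allow_zero && x == lower)) {
    cmp <- if (allow_zero) ">=" else ">"
    stop_liprisk(sprintf("`%s` must be %s %g (got %g)", name, cmp, lower, x),
                 "liprisk_parameter_error")
  }
  invisible(x)
}
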