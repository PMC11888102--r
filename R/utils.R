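#' @importFrom rlang abort %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Commercial rounding: .5 always rounds away from zero, as money is reported.
# base round() rounds half to even, which is wrong for dollar reports.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# run expr with a locally-set RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

assert_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name), class = "patientcost_invalid_argument")
  }
  if (x < min || x > max) {
    abort(
      sprintf("`%s` must be in [%s, %s], got %s", name, format(min), format(max), format(x)),
      class = "patientcost_invalid_argument"
    )
  }
  invisible(x)
}

config_error <- function(msg) abort(msg, class = "patientcost_configuration_error")
schema_error <- function(msg) abort(msg, class = "patientcost_schema_error")
validation_error <- function(msg) abort(msg, class = "patientcost_validation_error")
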