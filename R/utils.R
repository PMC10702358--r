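# Unit conversion factors, kept in one place: volume unit mistakes are the
# dominant bug risk in the loading arithmetic.
UL_TO_UM3 <- 1e9   # 1 microlitre = 1e9 cubic micrometres
ML_TO_UM3 <- 1e12  # 1 millilitre = 1e12 cubic micrometres

# Round half away from zero (reporting convention for integer percentages;
# base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`,
#' restoring the previous RNG state afterwards, so that package simulations
#' are reproducible without disturbing the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

stop_input <- function(...) abort(paste0(...), class = "gelbead_input_error")

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_input("`", name, "` must be a single positive finite number")
  }
  invisible(x)
}
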