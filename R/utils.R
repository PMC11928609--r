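# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the RNG seeded at \code{seed}, then restores the
#' caller's RNG state so library functions do not perturb user-level
#' reproducibility. A \code{NULL} seed evaluates the code under the current
#' RNG stream.
#'
#' @param seed integer seed or \code{NULL}.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_config <- function(msg) {
  stop(structure(class = c("mrpath_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_empty <- function(msg) {
  stop(structure(class = c("mrpath_empty_result", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Two-sided normal p-value for a z-ratio.
pval_normal <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

# Two-sided t p-value.
pval_t <- function(beta, se, df) 2 * stats::pt(-abs(beta / se), df = df)
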