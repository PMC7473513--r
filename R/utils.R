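# Internal helpers shared across modules.

# 90% crossing offset of a Boltzmann sigmoid: t0 +/- log(9)*dx.
LN9 <- log(9)
# 10%->90% rise time: log(81)*dx.
LN81 <- log(81)

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded package functions never disturb the global random stream.
#' A `NULL` seed leaves the RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Truncated normal draws by inverse-CDF; deterministic under set.seed().
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower < upper)
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# Odd-window running-median smoothing; k <= 1 or short input returns x.
median_smooth <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L || length(x) < k) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

# Robust per-sample noise scale from first differences (signal-insensitive
# for slowly varying traces).
diff_noise_sd <- function(x) {
  if (length(x) < 3L) return(0)
  stats::mad(diff(x)) / sqrt(2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(
    class = c("ek_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
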