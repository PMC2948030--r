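## Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Restores the caller's `.Random.seed` afterwards so that seeded internals
#' never perturb the user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = env)
      else if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a child seed from a parent seed and an index, staying in int range
#' @noRd
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(index) * 7919) %% 2147483629)
}

stop_if_not <- function(cond, msg, class = "fcparcel_error") {
  if (!cond) stop(errorCondition(msg, class = c(class, "error", "condition")))
  invisible(TRUE)
}

check_finite <- function(x, what = "array") {
  stop_if_not(all(is.finite(x)), sprintf("non-finite values in %s", what),
              class = "fcparcel_nonfinite_error")
}

#' Z-normalize a vector to mean 0, sd 1 (population sd uses n-1 denominator)
#' @noRd
znorm <- function(x) {
  s <- stats::sd(x)
  stop_if_not(s > 0, "cannot z-normalize a constant series",
              class = "fcparcel_degenerate_error")
  (x - mean(x)) / s
}

#' Linear index <-> voxel coordinate maps for a 3-D grid
#' @noRd
grid_coords <- function(dim3) {
  as.matrix(expand.grid(x = seq_len(dim3[1]), y = seq_len(dim3[2]),
                        z = seq_len(dim3[3])))
}
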