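#' @importFrom stats lm coef sd rnorm runif aov anova TukeyHSD median setNames
#' @importFrom rlang .data abort
#' @import tibble
NULL

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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

# Derive a reproducible child seed from a parent seed; kept below 2^31.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

stop_input <- function(msg) {
  abort(msg, class = "arterydmri_input_error")
}

# Symmetric 3x3 tensor from its 6 unique elements (xx, yy, zz, xy, xz, yz).
tensor_from_elements <- function(el) {
  matrix(c(el[1], el[4], el[5],
           el[4], el[2], el[6],
           el[5], el[6], el[3]), 3, 3)
}

tensor_to_elements <- function(D) {
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

# Quadratic-form design row(s) for unit directions: g' D g as a linear form in
# the 6 unique tensor elements (xx, yy, zz, xy, xz, yz).
quadratic_design <- function(g) {
  g <- matrix(g, ncol = 3)
  cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
        2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}
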