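#' Gradient scheme objects
#'
#' A gradient scheme is the acquisition contract shared by the phantom
#' generator and all fitters: one row per measurement with the diffusion
#' weighting `b` (s/mm^2), the unit gradient direction (`gx`, `gy`, `gz`),
#' and a `is_b0` flag, plus the pulse timings delta (gradient duration, ms)
#' and Delta (gradient separation, ms) stored as attributes.
#'
#' @param b numeric vector of b-values (s/mm^2), non-negative.
#' @param directions numeric matrix (n x 3) of gradient directions; rows for
#'   b = 0 entries may be zero vectors, all other rows must have unit norm.
#' @param delta_small gradient pulse duration delta (ms).
#' @param delta_big gradient separation Delta (ms); must exceed `delta_small`.
#' @param label protocol name.
#'
#' @return A tibble of class `gradient_scheme` with columns
#'   `b`, `gx`, `gy`, `gz`, `is_b0` and attributes `delta_small`,
#'   `delta_big`, `label`.
#' @export
gradient_scheme <- function(b, directions, delta_small, delta_big,
                            label = "custom") {
  directions <- matrix(as.numeric(directions), ncol = 3)
  b <- as.numeric(b)
  if (nrow(directions) != length(b)) {
    stop_input("`b` and `directions` must have the same length")
  }
  if (any(b < 0)) stop_input("b-values must be non-negative")
  if (!(delta_small < delta_big)) {
    stop_input("gradient duration delta must be smaller than separation Delta")
  }
  is_b0 <- b == 0
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm[!is_b0] - 1) > 1e-9)) {
    stop_input("non-b0 gradient directions must have unit norm (within 1e-9)")
  }
  out <- tibble::tibble(
    b = b, gx = directions[, 1], gy = directions[, 2], gz = directions[, 3],
    is_b0 = is_b0
  )
  attr(out, "delta_small") <- delta_small
  attr(out, "delta_big") <- delta_big
  attr(out, "label") <- label
  class(out) <- c("gradient_scheme", class(out))
  out
}

#' @export
print.gradient_scheme <- function(x, ...) {
  shells <- sort(unique(x$b[!x$is_b0]))
  cat(sprintf(
    "<gradient_scheme '%s'>  %d measurements (%d b0), shells: %s s/mm^2\n",
    attr(x, "label"), nrow(x), sum(x$is_b0),
    paste(shells, collapse = ", ")
  ))
  cat(sprintf("  delta = %.2f ms, Delta = %.2f ms\n",
              attr(x, "delta_small"), attr(x, "delta_big")))
  invisible(x)
}

scheme_directions <- function(scheme) {
  cbind(scheme$gx, scheme$gy, scheme$gz)
}

#' Generate approximately uniform gradient directions
#'
#' Produces `n` unit vectors on the upper hemisphere by iterative
#' electrostatic-repulsion descent: the points (together with their
#' antipodes) repel each other with an inverse-square force, so the energy
#' sum of 1/||gi - gj|| + 1/||gi + gj|| over pairs is driven to a local
#' minimum. Reproducible for a fixed seed.
#'
#' @param n number of directions (>= 1).
#' @param seed integer seed for the random starting configuration.
#' @param n_iter number of descent iterations.
#' @return n x 3 matrix of unit row vectors with non-negative z.
#' @export
generate_directions <- function(n, seed = 1L, n_iter = 400L) {
  if (length(n) != 1 || is.na(n) || n < 1) {
    stop_input("`n` must be a positive integer")
  }
  n <- as.integer(n)
  key <- paste(n, seed, n_iter, sep = "_")
  cached <- .direction_cache[[key]]
  if (!is.null(cached)) return(cached)
  g <- with_seed(seed, {
    matrix(rnorm(3 * n), n, 3)
  })
  g <- g / sqrt(rowSums(g^2))
  if (n > 1) {
    step <- 0.05
    for (it in seq_len(n_iter)) {
      # pairwise separations to the other points and to their antipodes
      dx1 <- outer(g[, 1], g[, 1], "-")
      dy1 <- outer(g[, 2], g[, 2], "-")
      dz1 <- outer(g[, 3], g[, 3], "-")
      dx2 <- outer(g[, 1], g[, 1], "+")
      dy2 <- outer(g[, 2], g[, 2], "+")
      dz2 <- outer(g[, 3], g[, 3], "+")
      r1 <- sqrt(dx1^2 + dy1^2 + dz1^2)
      r2 <- sqrt(dx2^2 + dy2^2 + dz2^2)
      diag(r1) <- Inf
      diag(r2) <- Inf
      w1 <- 1 / pmax(r1, 1e-6)^3
      w2 <- 1 / pmax(r2, 1e-6)^3
      f <- cbind(rowSums(dx1 * w1) + rowSums(dx2 * w2),
                 rowSums(dy1 * w1) + rowSums(dy2 * w2),
                 rowSums(dz1 * w1) + rowSums(dz2 * w2))
      # project force onto the tangent plane, take a step, renormalise
      f <- f - g * rowSums(f * g)
      fmax <- max(sqrt(rowSums(f^2)))
      if (fmax < 1e-12) break
      g <- g + step * f / fmax
      g <- g / sqrt(rowSums(g^2))
      if (it %% 50 == 0) step <- step * 0.7
    }
  }
  flip <- g[, 3] < 0 | (g[, 3] == 0 & g[, 1] < 0)
  g[flip, ] <- -g[flip, , drop = FALSE]
  g <- g / sqrt(rowSums(g^2))
  .direction_cache[[key]] <- g
  g
}

# session cache: repeated calls (e.g. the kurtosis direction sample per
# voxel) reuse the optimised set
.direction_cache <- new.env(parent = emptyenv())

# Seeded ordering of DW entries such that consecutive DW measurements differ
# in b-value by at least `min_gap` (heat-load balancing of the sequence).
shuffle_dw_entries <- function(bvals, min_gap = 600, seed = 1L,
                               max_attempts = 200L) {
  n <- length(bvals)
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      remaining <- seq_len(n)
      order_idx <- integer(0)
      prev_b <- NA_real_
      ok <- TRUE
      for (k in seq_len(n)) {
        cand <- if (is.na(prev_b)) remaining else {
          remaining[abs(bvals[remaining] - prev_b) >= min_gap]
        }
        if (length(cand) == 0) {
          ok <- FALSE
          break
        }
        pick <- cand[sample.int(length(cand), 1L)]
        order_idx <- c(order_idx, pick)
        remaining <- setdiff(remaining, pick)
        prev_b <- bvals[pick]
      }
      if (ok) return(order_idx)
    }
    stop_input("could not construct a b-value-separated measurement order")
  })
}

# Insert n_b0 b0 entries evenly through a DW sequence of length n_dw.
interleave_b0 <- function(n_dw, n_b0) {
  total <- n_dw + n_b0
  b0_pos <- unique(round(seq(1, total, length.out = n_b0)))
  while (length(b0_pos) < n_b0) {
    gap <- setdiff(seq_len(total), b0_pos)
    b0_pos <- sort(c(b0_pos, gap[1]))
  }
  is_b0 <- rep(FALSE, total)
  is_b0[b0_pos] <- TRUE
  is_b0
}

#' Build the high multi b-value (HMb) acquisition scheme
#'
#' Twelve shells at b = 100, 200, 300, 600, 900, 1200, 1500, 1800, 2100,
#' 2400, 2700, 3000 s/mm^2 with 12 diffusion-encoding directions per shell
#' and 121 interleaved b0 measurements (265 entries in total), with pulse
#' timings delta = 3.55 ms and Delta = 8.52 ms. The measurement order is a
#' seeded pseudo-random sequence in which consecutive diffusion-weighted
#' entries differ in b-value by at least 600 s/mm^2 and b0 scans are spread
#' evenly through the run.
#'
#' @param seed integer seed controlling the direction set and the ordering.
#' @return A [gradient_scheme()].
#' @export
build_hmb_scheme <- function(seed = 1L) {
  shells <- c(100, 200, 300, 600, 900, 1200, 1500, 1800, 2100, 2400, 2700, 3000)
  dirs <- generate_directions(12, seed = child_seed(seed, 1))
  b_dw <- rep(shells, each = 12)
  g_dw <- dirs[rep(seq_len(12), times = length(shells)), ]
  ord <- shuffle_dw_entries(b_dw, min_gap = 600, seed = child_seed(seed, 2))
  b_dw <- b_dw[ord]
  g_dw <- g_dw[ord, ]
  is_b0 <- interleave_b0(length(b_dw), 121L)
  n <- length(is_b0)
  b <- numeric(n)
  g <- matrix(0, n, 3)
  b[!is_b0] <- b_dw
  g[!is_b0, ] <- g_dw
  gradient_scheme(b, g, delta_small = 3.55, delta_big = 8.52, label = "HMb")
}

#' Build the high angular resolution (HAR) acquisition scheme
#'
#' Three shells at b = 800, 1600 and 2200 s/mm^2 with 96 diffusion-encoding
#' directions per shell plus their polarity-reversed copies (192
#' diffusion-weighted entries per shell) and 20 b0 measurements per shell
#' (636 entries in total); delta = 3.55 ms, Delta = 8.52 ms. Entries are
#' ordered by a seeded shuffle with b0 scans spread evenly.
#'
#' @param seed integer seed controlling the direction set and the ordering.
#' @return A [gradient_scheme()].
#' @export
build_har_scheme <- function(seed = 1L) {
  shells <- c(800, 1600, 2200)
  base <- generate_directions(96, seed = child_seed(seed, 3))
  dirs <- rbind(base, -base)
  b_dw <- rep(shells, each = nrow(dirs))
  g_dw <- dirs[rep(seq_len(nrow(dirs)), times = length(shells)), ]
  ord <- with_seed(child_seed(seed, 4), sample.int(length(b_dw)))
  b_dw <- b_dw[ord]
  g_dw <- g_dw[ord, ]
  is_b0 <- interleave_b0(length(b_dw), 60L)
  n <- length(is_b0)
  b <- numeric(n)
  g <- matrix(0, n, 3)
  b[!is_b0] <- b_dw
  g[!is_b0, ] <- g_dw
  gradient_scheme(b, g, delta_small = 3.55, delta_big = 8.52, label = "HAR")
}

#' Write / read a gradient scheme as TSV
#'
#' Columns `b`, `gx`, `gy`, `gz`, `is_b0`; pulse timings and the protocol
#' label are stored in commented header lines.
#'
#' @param scheme a [gradient_scheme()].
#' @param path file path.
#' @return `write_scheme_tsv` returns `path` invisibly; `read_scheme_tsv`
#'   returns a [gradient_scheme()].
#' @export
write_scheme_tsv <- function(scheme, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# label: %s", attr(scheme, "label")),
    sprintf("# delta_small: %.10g", attr(scheme, "delta_small")),
    sprintf("# delta_big: %.10g", attr(scheme, "delta_big"))
  ), con)
  utils::write.table(
    data.frame(b = scheme$b, gx = scheme$gx, gy = scheme$gy, gz = scheme$gz,
               is_b0 = scheme$is_b0),
    con, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_scheme_tsv
#' @export
read_scheme_tsv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(name) {
    line <- grep(paste0("^# ", name, ":"), hdr, value = TRUE)
    sub(paste0("^# ", name, ": *"), "", line[1])
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  gradient_scheme(
    b = tab$b, directions = as.matrix(tab[, c("gx", "gy", "gz")]),
    delta_small = as.numeric(get_field("delta_small")),
    delta_big = as.numeric(get_field("delta_big")),
    label = get_field("label")
  )
}
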