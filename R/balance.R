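#' Grid cell indices of profiles
#'
#' Discretizes each feature dimension of `[0,1]` into `grid_size` equidistant
#' bins: index `floor(value * grid_size)`, with `value == 1` clamped into the
#' last bin (the upper bin is closed). The tuple of per-dimension indices
#' identifies a cell of the conceptual `grid_size^D` grid; only occupied
#' cells are ever stored.
#'
#' @param x A profile tibble or numeric matrix with values in `[0,1]`.
#' @param grid_size Number of grid cells per feature dimension (G >= 1).
#' @return An integer matrix of cell indices in `[0, grid_size)`, same shape
#'   as the feature matrix.
#' @export
grid_cell <- function(x, grid_size = 10L) {
  m <- profile_matrix(x)
  stopifnot(grid_size >= 1, grid_size == round(grid_size))
  if (anyNA(m) || any(m < 0) || any(m > 1)) {
    kb_stop("profile values must lie in [0, 1]", "kbalance_range_error")
  }
  idx <- floor(m * grid_size)
  idx[idx >= grid_size] <- grid_size - 1  # value == 1.0 falls in the last bin
  storage.mode(idx) <- "integer"
  idx
}

# collision-free character key per row of a cell-index matrix
grid_cell_keys <- function(x, grid_size) {
  idx <- grid_cell(x, grid_size)
  apply(idx, 1L, paste, collapse = ",")
}

#' Balance a training set over feature space
#'
#' Label-blind undersampling that flattens the density of training samples
#' over the discretized k-mer feature space. Samples are streamed in a
#' seeded random permutation (without replacement). The first
#' `floor(init_fraction * budget)` stream elements are accepted
#' unconditionally to initialise the grid. Each later candidate in cell `g`
#' is accepted if its current cell count `C_g` is below the running maximum
#' cell count `C_max` (empty and sparse regions fill up preferentially) and
#' rejected if `C_g == C_max`; a rejected sample is discarded permanently.
#' After `escape_threshold` consecutive rejections the next candidate is
#' accepted unconditionally, so the stream cannot stall in saturated
#' regions. The loop stops when `budget` samples have been accepted or the
#' stream is exhausted.
#'
#' @param profiles A profile tibble ([kmer_profiles()]) or numeric matrix
#'   with values in `[0,1]`.
#' @param budget Target number of accepted samples, N.
#' @param grid_size Grid cells per feature dimension, G (default 10).
#' @param init_fraction Fraction of N accepted unconditionally at the start
#'   (default 0.3).
#' @param escape_threshold Consecutive rejections before a forced
#'   acceptance (default 10).
#' @param seed RNG seed for the candidate permutation.
#' @param stream Optional explicit candidate order (a permutation of row
#'   indices); overrides the seeded permutation. Intended for testing and
#'   for replaying a run.
#' @return An object of class `kb_balance` with elements
#'   \describe{
#'     \item{accepted}{row indices into `profiles`, in acceptance order}
#'     \item{accepted_ids}{their `id`s, when the input carries them}
#'     \item{diagnostics}{per-cell tibble: `cell`, `c_before`, `c_after`,
#'       `c_bar` = (before+after)/2, `delta_c` = after-before}
#'     \item{n_escape, n_reject}{escape-hatch acceptances and total
#'       rejections}
#'     \item{config}{the resolved balancing parameters}
#'   }
#'   `tidy()` returns the diagnostics, `glance()` a one-row summary, and
#'   `autoplot()` the density-removal diagnostic plot.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(400), 100, 4)
#' b <- balance_profiles(x, budget = 50, grid_size = 4, seed = 1)
#' glance(b)
#' @export
balance_profiles <- function(profiles, budget, grid_size = 10L,
                             init_fraction = 0.3, escape_threshold = 10L,
                             seed = 1L, stream = NULL) {
  m <- profile_matrix(profiles)
  n <- nrow(m)
  if (n < 1) kb_stop("empty input", "kbalance_empty_input")
  stopifnot(budget >= 1, budget == round(budget),
            init_fraction >= 0, init_fraction < 1,
            escape_threshold >= 1)
  budget <- as.integer(budget)
  if (budget > n) {
    warn(paste0("budget N = ", budget, " exceeds the ", n,
                " available samples"))
  }
  keys <- grid_cell_keys(m, grid_size)
  seeded_stream <- is.null(stream)
  if (seeded_stream) {
    set.seed(seed)
    stream <- sample.int(n)
  } else {
    stream <- as.integer(stream)
    stopifnot(all(stream >= 1), all(stream <= n), !anyDuplicated(stream))
  }

  counts <- new.env(hash = TRUE, parent = emptyenv())
  c_max <- 0L
  accepted <- integer(min(budget, n))
  n_acc <- 0L
  n_init <- min(floor(init_fraction * budget), n)
  rej_run <- 0L
  n_escape <- 0L
  n_reject <- 0L

  for (pos in seq_along(stream)) {
    if (n_acc >= budget) break
    i <- stream[[pos]]
    key <- keys[[i]]
    cg <- get0(key, envir = counts, ifnotfound = 0L)
    escape <- FALSE
    if (pos <= n_init) {
      take <- TRUE
    } else if (rej_run >= escape_threshold) {
      take <- TRUE
      escape <- TRUE
    } else {
      take <- cg < c_max
    }
    if (take) {
      assign(key, cg + 1L, envir = counts)
      if (cg + 1L > c_max) c_max <- cg + 1L
      n_acc <- n_acc + 1L
      accepted[[n_acc]] <- i
      rej_run <- 0L
      if (escape) n_escape <- n_escape + 1L
    } else {
      n_reject <- n_reject + 1L
      rej_run <- rej_run + 1L
    }
  }
  accepted <- accepted[seq_len(n_acc)]

  before <- table(keys)
  after <- table(factor(keys[accepted], levels = names(before)))
  diagnostics <- tibble(
    cell = names(before),
    c_before = as.integer(before),
    c_after = as.integer(after)
  )
  diagnostics$c_bar <- (diagnostics$c_before + diagnostics$c_after) / 2
  diagnostics$delta_c <- diagnostics$c_after - diagnostics$c_before

  structure(
    list(
      accepted = accepted,
      accepted_ids = if (!is.null(rownames(m))) rownames(m)[accepted],
      diagnostics = diagnostics,
      c_max = c_max,
      n_escape = n_escape,
      n_reject = n_reject,
      config = list(
        budget = budget, grid_size = as.integer(grid_size),
        init_fraction = init_fraction,
        escape_threshold = as.integer(escape_threshold),
        seed = if (seeded_stream) seed else NA_integer_,
        n_input = n
      )
    ),
    class = "kb_balance"
  )
}

#' Per-cell balancing diagnostics
#'
#' One row per grid cell occupied in the full input, sorted by decreasing
#' average occupancy `c_bar = (c_before + c_after) / 2`, with
#' `delta_c = c_after - c_before` (never positive: balancing only removes
#' samples). Suitable for log-log plotting of `c_bar` against `-delta_c`.
#'
#' @param result A `kb_balance` object from [balance_profiles()].
#' @return A tibble with columns `cell`, `c_before`, `c_after`, `c_bar`,
#'   `delta_c`.
#' @export
balance_diagnostics <- function(result) {
  stopifnot(inherits(result, "kb_balance"))
  dplyr::arrange(result$diagnostics, dplyr::desc(.data$c_bar))
}

#' @method tidy kb_balance
#' @export
tidy.kb_balance <- function(x, ...) balance_diagnostics(x)

#' @method glance kb_balance
#' @export
glance.kb_balance <- function(x, ...) {
  tibble(
    n_input = x$config$n_input,
    n_accepted = length(x$accepted),
    n_cells = nrow(x$diagnostics),
    c_max = x$c_max,
    n_escape = x$n_escape,
    n_reject = x$n_reject
  )
}

#' @export
print.kb_balance <- function(x, ...) {
  cat("<kb_balance> feature-space balancing result\n")
  cat("  accepted ", length(x$accepted), " of ", x$config$n_input,
      " samples (budget N = ", x$config$budget,
      ", G = ", x$config$grid_size, ")\n", sep = "")
  cat("  occupied cells: ", nrow(x$diagnostics),
      "; C_max = ", x$c_max,
      "; rejections = ", x$n_reject,
      "; escape acceptances = ", x$n_escape, "\n", sep = "")
  invisible(x)
}

#' @method autoplot kb_balance
#' @export
autoplot.kb_balance <- function(object, ...) {
  d <- balance_diagnostics(object)
  d <- d[d$c_bar > 0 & d$delta_c < 0, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$c_bar, y = -.data$delta_c)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(bar(C) == (C[before] + C[after]) / 2),
      y = expression(-Delta * C ~ "(samples removed per cell)"),
      title = "Samples removed per grid cell vs cell density"
    ) +
    ggplot2::theme_minimal()
}
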