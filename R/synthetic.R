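#' Define a synthetic sequence class
#'
#' A class is a first-order Markov chain over A,C,G,T with a sampling
#' weight. Sequences drawn from different classes then differ in their
#' k-mer statistics for every k >= 1, which makes the classes learnable
#' from k-mer profiles.
#'
#' @param label Class (taxon) label.
#' @param transition 4x4 row-stochastic transition matrix, rows/columns in
#'   A,C,G,T order.
#' @param initial Length-4 stochastic vector of initial base probabilities.
#' @param weight Relative sampling proportion (> 0); weights are normalised
#'   across classes.
#' @return A `kb_class_model` list.
#' @export
class_model <- function(label, transition, initial, weight = 1) {
  stopifnot(is.character(label), nzchar(label))
  transition <- as.matrix(transition)
  initial <- as.numeric(initial)
  if (!all(dim(transition) == c(4, 4)) || length(initial) != 4) {
    kb_stop("transition must be 4x4 and initial length 4", "kbalance_type_error")
  }
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-12)) {
    kb_stop("transition rows must be non-negative and sum to 1",
            "kbalance_range_error")
  }
  if (any(initial < 0) || abs(sum(initial) - 1) > 1e-12) {
    kb_stop("initial must be a stochastic vector", "kbalance_range_error")
  }
  if (!is.numeric(weight) || weight <= 0) {
    kb_stop("weight must be > 0", "kbalance_range_error")
  }
  dimnames(transition) <- list(DNA_BASES, DNA_BASES)
  names(initial) <- DNA_BASES
  structure(list(label = label, transition = transition,
                 initial = initial, weight = weight),
            class = "kb_class_model")
}

#' GC-content-parameterised class model
#'
#' Builds a class whose stationary base composition has the requested GC
#' content, with a "stickiness" term mixing in self-transitions:
#' `P = stickiness * I + (1 - stickiness) * rep(pi)`, where
#' `pi = ((1-gc)/2, gc/2, gc/2, (1-gc)/2)`. Since every row mixes the same
#' stationary vector, `pi` is exact regardless of stickiness. Stickiness
#' produces low-complexity runs (homopolymer-enriched k-mer profiles), so
#' per-sequence profiles spread over many grid cells instead of collapsing
#' into one — the density structure the balancing step operates on.
#'
#' @param label Class label.
#' @param gc Target GC content in (0, 1).
#' @param stickiness Self-transition mixture weight in `[0, 1)`; default 0.6.
#' @param weight Sampling proportion.
#' @return A `kb_class_model`.
#' @export
gc_class_model <- function(label, gc, stickiness = 0.6, weight = 1) {
  stopifnot(gc > 0, gc < 1, stickiness >= 0, stickiness < 1)
  pi <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  transition <- stickiness * diag(4) +
    (1 - stickiness) * matrix(pi, 4, 4, byrow = TRUE)
  class_model(label, transition, initial = pi, weight = weight)
}

#' Specification of a synthetic labelled dataset
#'
#' @param classes List of [class_model()]s.
#' @param n_total Total number of sequences; class counts are drawn
#'   multinomially from the normalised class weights.
#' @param length Sequence length in nucleotides (default 1500).
#' @param seed RNG seed; generation is fully determined by it.
#' @return A `kb_synthetic_spec`.
#' @export
synthetic_spec <- function(classes, n_total, length = 1500L, seed = 0L) {
  stopifnot(is.list(classes), length(classes) >= 1)
  ok <- vapply(classes, inherits, TRUE, what = "kb_class_model")
  if (!all(ok)) kb_stop("classes must be kb_class_model objects",
                        "kbalance_type_error")
  stopifnot(n_total >= length(classes), length >= 1)
  structure(
    list(classes = classes, n_total = as.integer(n_total),
         length = as.integer(length), seed = as.integer(seed)),
    class = "kb_synthetic_spec"
  )
}

#' Built-in benchmark dataset specifications
#'
#' Two presets over the same four GC-parameterised classes
#' (GC targets 0.30, 0.43, 0.57, 0.70; labels `gc30`..`gc70`):
#' \describe{
#'   \item{separated4}{equal class weights; the classes are well separated
#'     in k-mer space, a clean multi-class benchmark.}
#'   \item{blob_imbalanced}{the `gc43` class carries 85% of the sampling
#'     weight (5% each for the rest), so one region of feature space is
#'     densely covered while the others are sparse — the pathology the
#'     balancing step is designed to correct.}
#' }
#'
#' @param name `"separated4"` or `"blob_imbalanced"`.
#' @param n_total Total sequences (default 2800).
#' @param length Sequence length (default 1500).
#' @param seed RNG seed.
#' @return A `kb_synthetic_spec`; pass it to [generate_dataset()].
#' @export
preset_benchmark <- function(name, n_total = 2800L, length = 1500L, seed = 0L) {
  name <- match.arg(name, c("separated4", "blob_imbalanced"))
  gc <- c(gc30 = 0.30, gc43 = 0.43, gc57 = 0.57, gc70 = 0.70)
  # alternating run-length texture: classes adjacent in GC differ in a
  # higher-order statistic too, as real taxa do
  stickiness <- c(0.65, 0.55, 0.65, 0.55)
  weights <- if (name == "separated4") {
    rep(1, 4)
  } else {
    c(0.05, 0.85, 0.05, 0.05)  # gc43 is the dense blob
  }
  classes <- purrr::map(seq_along(gc), function(i) {
    gc_class_model(names(gc)[[i]], gc[[i]], stickiness = stickiness[[i]],
                   weight = weights[[i]])
  })
  synthetic_spec(classes, n_total = n_total, length = length, seed = seed)
}

#' Generate a labelled synthetic dataset
#'
#' Draws class counts multinomially from the class weights, simulates each
#' sequence from its class's Markov chain, and shuffles the rows (all under
#' the spec's seed, so identical specs give identical datasets).
#'
#' @param spec A `kb_synthetic_spec` from [synthetic_spec()] or
#'   [preset_benchmark()].
#' @return A tibble with columns `id`, `sequence`, `label`; every sequence
#'   has exactly `spec$length` nucleotides.
#' @examples
#' d <- generate_dataset(preset_benchmark("separated4", n_total = 40, seed = 1))
#' table(d$label)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "kb_synthetic_spec"))
  set.seed(spec$seed)
  w <- vapply(spec$classes, function(cl) cl$weight, 0)
  counts <- as.integer(stats::rmultinom(1, spec$n_total, w / sum(w)))
  seqs <- character(0)
  labels <- character(0)
  for (i in seq_along(spec$classes)) {
    if (counts[[i]] == 0) next
    cl <- spec$classes[[i]]
    seqs <- c(seqs, simulate_markov(counts[[i]], spec$length,
                                    cl$initial, cl$transition))
    labels <- c(labels, rep(cl$label, counts[[i]]))
  }
  ord <- sample.int(length(seqs))
  tibble(
    id = sprintf("synth%06d", seq_along(seqs)),
    sequence = seqs[ord],
    label = labels[ord]
  )
}

# vectorised first-order chain: one transition step per position across all
# sequences of the class
simulate_markov <- function(n, len, initial, transition) {
  states <- matrix(0L, n, len)
  states[, 1] <- sample.int(4L, n, replace = TRUE, prob = initial)
  if (len > 1) {
    cum <- t(apply(transition, 1, cumsum))
    cum[, 4] <- 1  # guard against rounding
    for (t in 2:len) {
      u <- runif(n)
      prev <- states[, t - 1]
      nxt <- integer(n)
      for (s in 1:4) {
        sel <- prev == s
        if (any(sel)) nxt[sel] <- findInterval(u[sel], cum[s, ]) + 1L
      }
      states[, t] <- nxt
    }
  }
  apply(states, 1, function(r) paste(DNA_BASES[r], collapse = ""))
}
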