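# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals.

# dictionary-count over all sliding windows; windows with non-ACGT skipped
naive_kmer_profile <- function(seq, k) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < k) return(NULL)
  words <- substring(seq, 1:(L - k + 1), k:L)
  words <- words[!grepl("[^ACGT]", words)]
  if (length(words) == 0) return(NULL)
  counts <- table(factor(words, levels = kmer_words(k)))
  as.numeric(counts) / length(words)
}

# dense-array replay of the balancing stream for low-dimensional inputs;
# materialises the full grid_size^D count array
dense_balance_oracle <- function(x, budget, grid_size, init_fraction = 0.3,
                                 escape_threshold = 10, seed = 1) {
  n <- nrow(x)
  d <- ncol(x)
  idx <- floor(x * grid_size)
  idx[idx >= grid_size] <- grid_size - 1
  counts <- array(0L, dim = rep(grid_size, d))
  set.seed(seed)
  stream <- sample.int(n)
  c_max <- 0L
  accepted <- integer(0)
  n_init <- min(floor(init_fraction * budget), n)
  rej <- 0L
  for (pos in seq_along(stream)) {
    if (length(accepted) >= budget) break
    i <- stream[pos]
    cell <- matrix(idx[i, ] + 1L, nrow = 1)
    cg <- counts[cell]
    take <- pos <= n_init || rej >= escape_threshold || cg < c_max
    if (take) {
      counts[cell] <- cg + 1L
      c_max <- max(c_max, cg + 1L)
      accepted <- c(accepted, i)
      rej <- 0L
    } else {
      rej <- rej + 1L
    }
  }
  accepted
}

# per-class precision computed independently of confusion_tally
naive_map <- function(truth, pred) {
  classes <- sort(unique(c(truth, pred)))
  prec <- vapply(classes, function(cl) {
    n_pred <- sum(pred == cl)
    if (n_pred == 0) 0 else sum(pred == cl & truth == cl) / n_pred
  }, 0)
  mean(prec)
}

random_dna <- function(len, n_prob = 0.05) {
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(rep((1 - n_prob) / 4, 4), n_prob)),
        collapse = "")
}

write_tmp <- function(lines, ext = ".txt") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
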