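PIPELINE_STAGES <- c(profile = 11L, balance = 23L, train = 37L,
                     predict = 41L, evaluate = 53L, split = 61L)

#' Derive a per-stage seed from a master seed
#'
#' Every pipeline stage uses its own deterministic seed so a stage can be
#' rerun in isolation. The scheme is
#' `(master * 2654435761 + stage offset) mod (2^31 - 1)` (Knuth
#' multiplicative hash, kept inside the 32-bit integer range).
#'
#' @param master Master seed (integer).
#' @param stage One of `"profile"`, `"balance"`, `"train"`, `"predict"`,
#'   `"evaluate"`, `"split"`.
#' @return An integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(stage %in% names(PIPELINE_STAGES))
  off <- PIPELINE_STAGES[[stage]]
  as.integer((as.numeric(master) %% 65536 * 2654435761 + off) %% (2^31 - 1))
}

#' Run the classification pipeline end to end
#'
#' Sequences to profiles, optional feature-space balancing of the training
#' split, classifier training, prediction on the test split, and
#' macro-average precision evaluation. Balancing is applied to the training
#' data only; test data are never balanced. The run is a pure function of
#' (inputs, configuration, seed): rerunning reproduces the report exactly.
#'
#' @param train A labelled tibble (`id`, `sequence`, `label`) for training,
#'   e.g. from [generate_dataset()] or [read_fasta()] + [join_labels()];
#'   alternatively a profile tibble with a `label` column (then `k` must
#'   match).
#' @param test Held-out data in the same form.
#' @param k k-mer word length (default 3, i.e. 64 features).
#' @param balance Whether to balance the training set (default TRUE).
#' @param budget Balancing budget N; required when `balance = TRUE`.
#' @param grid_size Grid cells per dimension G (default 10).
#' @param init_fraction,escape_threshold Balancing parameters, see
#'   [balance_profiles()].
#' @param family Classifier family, see [train_classifier()].
#' @param classifier Named list of extra arguments to [train_classifier()]
#'   (e.g. `n_learners`, `knn_k`).
#' @param seed Master seed; per-stage seeds are derived with
#'   [derive_seed()].
#' @param out_dir Optional directory; when given, all artifacts (profiles,
#'   accepted IDs, balancing diagnostics, model, predictions, report and
#'   the resolved configuration) are written there.
#' @return A `kb_pipeline_result`: list with `report` (a
#'   [macro_average_precision()] report), `predictions` (tibble id,
#'   truth, predicted), `balance` (`kb_balance` or NULL), `model`,
#'   `counts` (samples per stage) and `config`.
#' @examples
#' train <- generate_dataset(preset_benchmark("separated4", n_total = 120, seed = 1))
#' test <- generate_dataset(preset_benchmark("separated4", n_total = 60, seed = 2))
#' res <- run_pipeline(train, test, k = 2, balance = FALSE,
#'                     family = "subspace_knn", seed = 0)
#' glance(res$report)
#' @export
run_pipeline <- function(train, test, k = 3L, balance = TRUE, budget = NULL,
                         grid_size = 10L, init_fraction = 0.3,
                         escape_threshold = 10L,
                         family = "subspace_knn", classifier = list(),
                         seed = 0L, out_dir = NULL) {
  stopifnot(is.data.frame(train), is.data.frame(test))
  if (!"label" %in% names(train)) {
    kb_stop("training data must carry a `label` column", "kbalance_type_error")
  }
  if (balance && is.null(budget)) {
    kb_stop("`budget` (N) is required when balancing is enabled",
            "kbalance_type_error")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      kb_stop(paste0("pipeline stage '", name, "' failed: ",
                     conditionMessage(e)),
              "kbalance_pipeline_error")
    })
  }
  train_prof <- stage("profile",
                      if ("sequence" %in% names(train)) kmer_profiles(train, k)
                      else train)
  test_prof <- stage("profile",
                     if ("sequence" %in% names(test)) kmer_profiles(test, k)
                     else test)

  bal <- NULL
  train_used <- train_prof
  if (balance) {
    bal <- stage("balance", balance_profiles(
      train_prof, budget = budget, grid_size = grid_size,
      init_fraction = init_fraction, escape_threshold = escape_threshold,
      seed = derive_seed(seed, "balance")
    ))
    train_used <- train_prof[bal$accepted, , drop = FALSE]
    attr(train_used, "kmers") <- attr(train_prof, "kmers")
  }

  model <- stage("train", do.call(train_classifier, c(
    list(profiles = train_used, family = family,
         seed = derive_seed(seed, "train")),
    classifier
  )))
  predicted <- stage("predict", predict(model, test_prof))
  truth <- test_prof$label
  report <- stage("evaluate",
                  if (!is.null(truth)) macro_average_precision(truth, predicted))

  predictions <- tibble(id = test_prof$id, predicted = predicted)
  if (!is.null(truth)) predictions$truth <- truth

  config <- list(
    k = as.integer(k), balance = balance, budget = budget,
    grid_size = as.integer(grid_size), init_fraction = init_fraction,
    escape_threshold = as.integer(escape_threshold), family = family,
    classifier = classifier, seed = as.integer(seed),
    stage_seeds = lapply(setNames(nm = names(PIPELINE_STAGES)),
                         derive_seed, master = seed)
  )
  counts <- list(
    n_train_input = nrow(train), n_train_profiles = nrow(train_prof),
    n_train_used = nrow(train_used), n_test = nrow(test_prof)
  )
  inform(paste0("pipeline: ", counts$n_train_input, " train -> ",
                counts$n_train_profiles, " profiles -> ",
                counts$n_train_used, " used for training; ",
                counts$n_test, " test; MAP = ",
                if (!is.null(report)) format(report$map, digits = 4) else "NA"))
  result <- structure(
    list(report = report, predictions = predictions, balance = bal,
         model = model, counts = counts, config = config),
    class = "kb_pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_artifacts(result, train_prof,
                                                  test_prof, out_dir)
  result
}

write_pipeline_artifacts <- function(result, train_prof, test_prof, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_profiles(train_prof, file.path(out_dir, "train_profiles.tsv"))
  write_profiles(test_prof, file.path(out_dir, "test_profiles.tsv"))
  if (!is.null(result$balance)) {
    readr::write_tsv(tibble(id = train_prof$id[result$balance$accepted]),
                     file.path(out_dir, "accepted_ids.tsv"), progress = FALSE)
    readr::write_tsv(balance_diagnostics(result$balance),
                     file.path(out_dir, "balance_diagnostics.tsv"),
                     progress = FALSE)
  }
  save_model(result$model, file.path(out_dir, "model.rds"))
  readr::write_tsv(result$predictions, file.path(out_dir, "predictions.tsv"),
                   progress = FALSE)
  if (!is.null(result$report)) {
    jsonlite::write_json(
      list(map = result$report$map,
           n_undefined = result$report$n_undefined,
           per_class = result$report$per_class,
           counts = result$counts),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  jsonlite::write_json(result$config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.kb_pipeline_result <- function(x, ...) {
  cat("<kb_pipeline_result> ", x$config$family,
      ", k = ", x$config$k,
      ", balanced = ", x$config$balance, "\n", sep = "")
  cat("  training samples used: ", x$counts$n_train_used,
      " / ", x$counts$n_train_input, "\n", sep = "")
  if (!is.null(x$report)) {
    cat("  test MAP = ", format(x$report$map, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' @method glance kb_pipeline_result
#' @export
glance.kb_pipeline_result <- function(x, ...) {
  tibble(
    family = x$config$family, k = x$config$k, balanced = x$config$balance,
    n_train_used = x$counts$n_train_used, n_test = x$counts$n_test,
    map = if (!is.null(x$report)) x$report$map else NA_real_
  )
}

#' Sweep pipeline configurations
#'
#' Runs [run_pipeline()] over the Cartesian grid of the supplied parameter
#' vectors and returns one row per combination, with the test MAP and the
#' runtime. A failing combination is recorded in the `error` column and
#' the sweep continues.
#'
#' @param train,test Labelled data as in [run_pipeline()] (sequence form).
#' @param k,grid_size,budget,family,balance Vectors of values to cross.
#' @param classifier Extra classifier arguments applied to every run.
#' @param seed Master seed (shared across combinations).
#' @return A tibble with columns `k`, `grid_size`, `budget`, `balance`,
#'   `family`, `map`, `n_train_used`, `runtime_s`, `error`.
#' @export
sweep_pipeline <- function(train, test, k = 3L, grid_size = 10L,
                           budget = NULL, family = "subspace_knn",
                           balance = c(TRUE, FALSE), classifier = list(),
                           seed = 0L) {
  grid <- tidyr::expand_grid(
    k = k, grid_size = grid_size,
    budget = budget %||% NA_integer_,
    balance = balance, family = family
  )
  purrr::pmap(grid, function(k, grid_size, budget, balance, family) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      run_pipeline(train, test, k = k, balance = balance,
                   budget = if (is.na(budget)) NULL else budget,
                   grid_size = grid_size, family = family,
                   classifier = classifier, seed = seed),
      error = function(e) e
    )
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      tibble(k = k, grid_size = grid_size, budget = budget,
             balance = balance, family = family,
             map = NA_real_, n_train_used = NA_integer_,
             runtime_s = dt, error = conditionMessage(res))
    } else {
      tibble(k = k, grid_size = grid_size, budget = budget,
             balance = balance, family = family,
             map = res$report$map,
             n_train_used = res$counts$n_train_used,
             runtime_s = dt, error = NA_character_)
    }
  }) |> purrr::list_rbind()
}

#' Cross-validated pipeline evaluation
#'
#' Stratified v-fold cross-validation: within each class, samples are
#' assigned to folds in a seeded random rotation, so folds are disjoint,
#' cover every sample exactly once, and preserve class proportions. Each
#' fold is held out in turn while the pipeline runs on the rest.
#'
#' @param data A labelled tibble (`id`, `sequence`, `label`).
#' @param v Number of folds (default 5).
#' @param ... Passed to [run_pipeline()] (k, balance, budget, family, ...).
#' @param seed Master seed; fold assignment uses the derived `"split"` seed.
#' @return A tibble with one row per fold (`fold`, `n_test`, `map`) with
#'   the fold assignment vector in attribute `folds`.
#' @export
cv_pipeline <- function(data, v = 5L, ..., seed = 0L) {
  stopifnot(is.data.frame(data), "label" %in% names(data), v >= 2)
  n <- nrow(data)
  set.seed(derive_seed(seed, "split"))
  folds <- integer(n)
  for (cl in unique(data$label)) {
    idx <- which(data$label == cl)
    folds[idx] <- sample(rep_len(seq_len(v), length(idx)))
  }
  rows <- lapply(seq_len(v), function(f) {
    res <- run_pipeline(data[folds != f, , drop = FALSE],
                        data[folds == f, , drop = FALSE],
                        ..., seed = seed)
    tibble(fold = f, n_test = sum(folds == f), map = res$report$map)
  })
  out <- purrr::list_rbind(rows)
  attr(out, "folds") <- folds
  out
}
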