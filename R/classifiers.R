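CLASSIFIER_FAMILIES <- c("bagged_trees", "subspace_knn", "subspace_discriminant",
                         "svm_linear", "svm_gaussian", "svm_polynomial", "mlp")

# families that cannot be fit on a single class
NEED_TWO_CLASSES <- c("subspace_discriminant",
                      "svm_linear", "svm_gaussian", "svm_polynomial")

#' Train an ensemble classifier on k-mer profiles
#'
#' Fits one of the simple classifier families used in the pipeline on a
#' profile matrix. Ensembles vote with hard labels; ties are broken towards
#' the lowest index in the model's (lexicographically ordered) class list.
#' Defaults: bagged trees use 100 bootstrap-resampled `rpart` trees;
#' subspace KNN and subspace discriminant analysis use 30 members, each on
#' a random feature subset of size `ceiling(D/2)` (KNN with k = 10,
#' Euclidean distance); SVMs are single `e1071::svm` fits with internal
#' standardisation; the neural network has one hidden layer of 512 units
#' with standardised inputs and a fixed iteration cap.
#'
#' @param profiles A profile tibble ([kmer_profiles()]) or numeric matrix.
#' @param labels Taxon labels, one per row. If `profiles` has a `label`
#'   column it is used when `labels` is missing.
#' @param family One of `"bagged_trees"`, `"subspace_knn"`,
#'   `"subspace_discriminant"`, `"svm_linear"`, `"svm_gaussian"`,
#'   `"svm_polynomial"`, `"mlp"`.
#' @param n_learners Number of ensemble members (ensemble families).
#' @param subspace_dim Features per member (subspace families);
#'   default `ceiling(D/2)`.
#' @param knn_k Neighbours for the KNN members.
#' @param hidden_size Hidden-layer width for `mlp`.
#' @param bootstrap Whether bagged trees resample with replacement; with
#'   `bootstrap = FALSE` and `n_learners = 1` the model is a single
#'   decision tree.
#' @param seed RNG seed; training is deterministic given the seed.
#' @return A `kb_model` object. `predict()` on it returns hard labels.
#' @export
train_classifier <- function(profiles, labels = NULL,
                             family = "subspace_knn",
                             n_learners = NULL, subspace_dim = NULL,
                             knn_k = 10L, hidden_size = 512L,
                             bootstrap = TRUE, seed = 0L) {
  family <- match.arg(family, CLASSIFIER_FAMILIES)
  if (is.null(labels) && is.data.frame(profiles) && "label" %in% names(profiles)) {
    labels <- profiles$label
  }
  x <- profile_matrix(profiles)
  if (is.null(labels)) kb_stop("no labels supplied", "kbalance_type_error")
  labels <- as.character(labels)
  n <- nrow(x)
  d <- ncol(x)
  stopifnot(length(labels) == n)
  if (n < 2) kb_stop("need at least 2 training samples", "kbalance_type_error")
  if (anyNA(x) || any(!is.finite(x))) {
    kb_stop("features contain NA/NaN/Inf", "kbalance_range_error")
  }
  class_labels <- sort(unique(labels))
  if (length(class_labels) < 2 && family %in% NEED_TWO_CLASSES) {
    kb_stop(paste0(family, " requires at least 2 classes"),
            "kbalance_class_error")
  }
  n_learners <- n_learners %||%
    switch(family, bagged_trees = 100L, subspace_knn = 30L,
           subspace_discriminant = 30L, 1L)
  subspace_dim <- as.integer(subspace_dim %||% ceiling(d / 2))
  stopifnot(n_learners >= 1, subspace_dim >= 1, subspace_dim <= d, knn_k >= 1)

  set.seed(seed)
  y <- factor(labels, levels = class_labels)
  fitted <- if (length(class_labels) == 1) {
    list(kind = "constant", label = class_labels)
  } else {
    switch(
      family,
      bagged_trees = fit_bagged_trees(x, y, n_learners, bootstrap),
      subspace_knn = fit_subspace(x, y, n_learners, subspace_dim,
                                  kind = "knn", knn_k = knn_k),
      subspace_discriminant = fit_subspace(x, y, n_learners, subspace_dim,
                                           kind = "lda"),
      svm_linear = fit_svm(x, y, "linear"),
      svm_gaussian = fit_svm(x, y, "radial"),
      svm_polynomial = fit_svm(x, y, "polynomial"),
      mlp = fit_mlp(x, y, hidden_size)
    )
  }
  structure(
    list(
      spec = list(family = family, n_learners = n_learners,
                  subspace_dim = subspace_dim, knn_k = as.integer(knn_k),
                  hidden_size = as.integer(hidden_size),
                  bootstrap = bootstrap, seed = as.integer(seed)),
      class_labels = class_labels,
      fingerprint = list(d = d, features = colnames(x)),
      fitted = fitted,
      version = 1L
    ),
    class = "kb_model"
  )
}

fit_bagged_trees <- function(x, y, n_learners, bootstrap) {
  n <- nrow(x)
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  members <- lapply(seq_len(n_learners), function(j) {
    idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    d <- df[idx, , drop = FALSE]
    d$.y <- y[idx]
    rpart::rpart(.y ~ ., data = d, method = "class")
  })
  list(kind = "trees", members = members)
}

fit_subspace <- function(x, y, n_learners, subspace_dim, kind, knn_k = NULL) {
  d <- ncol(x)
  members <- lapply(seq_len(n_learners), function(j) {
    feats <- sort(sample.int(d, subspace_dim))
    if (kind == "knn") {
      list(features = feats, x = x[, feats, drop = FALSE], y = y,
           seed = sample.int(.Machine$integer.max, 1L))
    } else {
      sub <- x[, feats, drop = FALSE]
      keep <- apply(sub, 2, function(v) stats::sd(v) > 0)
      if (!any(keep)) keep[1] <- TRUE  # lda needs >= 1 non-constant column
      fit <- suppressWarnings(MASS::lda(sub[, keep, drop = FALSE], grouping = y))
      list(features = feats[keep], fit = fit)
    }
  })
  list(kind = kind, members = members, knn_k = knn_k)
}

fit_svm <- function(x, y, kernel) {
  keep <- apply(x, 2, function(v) stats::sd(v) > 0)
  fit <- e1071::svm(x[, keep, drop = FALSE], y, kernel = kernel, scale = TRUE)
  list(kind = "svm", fit = fit, keep = keep)
}

fit_mlp <- function(x, y, hidden_size) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  xs <- scale(x, center = mu, scale = sd)
  n_w <- (ncol(x) + 1) * hidden_size + (hidden_size + 1) * nlevels(y)
  fit <- nnet::nnet(xs, nnet::class.ind(y), size = hidden_size,
                    softmax = TRUE, MaxNWts = n_w + 1, maxit = 150,
                    decay = 1e-4, trace = FALSE)
  list(kind = "mlp", fit = fit, mu = mu, sd = sd, levels = levels(y))
}

#' Predict taxon labels with a trained model
#'
#' @param object A `kb_model` from [train_classifier()].
#' @param newdata A profile tibble or numeric matrix whose feature columns
#'   match the model's fingerprint (same k / feature ordering).
#' @param ... Unused.
#' @return A character vector of predicted labels, one per row (empty for
#'   zero rows). Only labels seen in training can be predicted.
#' @export
predict.kb_model <- function(object, newdata, ...) {
  x <- profile_matrix(newdata)
  if (ncol(x) != object$fingerprint$d) {
    kb_stop(paste0("feature dimension mismatch: model expects D = ",
                   object$fingerprint$d, ", got D = ", ncol(x)),
            "kbalance_fingerprint_error")
  }
  fp <- object$fingerprint$features
  if (!is.null(fp) && !is.null(colnames(x)) && !identical(colnames(x), fp)) {
    kb_stop("feature names do not match the model's k-mer fingerprint",
            "kbalance_fingerprint_error")
  }
  m <- nrow(x)
  if (m == 0) return(character(0))
  fitted <- object$fitted
  votes <- switch(
    fitted$kind,
    constant = matrix(fitted$label, m, 1),
    trees = {
      df <- as.data.frame(x)
      names(df) <- paste0("f", seq_len(ncol(x)))
      vapply(fitted$members, function(tr) {
        as.character(predict(tr, df, type = "class"))
      }, template_chr(m))
    },
    knn = vapply(fitted$members, function(mem) {
      set.seed(mem$seed)  # class::knn breaks exact ties at random
      as.character(class::knn(mem$x, x[, mem$features, drop = FALSE],
                              mem$y, k = fitted$knn_k))
    }, template_chr(m)),
    lda = vapply(fitted$members, function(mem) {
      as.character(predict(mem$fit, x[, mem$features, drop = FALSE])$class)
    }, template_chr(m)),
    svm = as.matrix(as.character(predict(fitted$fit,
                                         x[, fitted$keep, drop = FALSE]))),
    mlp = {
      xs <- scale(x, center = fitted$mu, scale = fitted$sd)
      p <- predict(fitted$fit, xs)
      as.matrix(fitted$levels[max.col(p, ties.method = "first")])
    }
  )
  votes <- matrix(votes, nrow = m)
  vote_labels(votes, object$class_labels)
}

template_chr <- function(m) character(m)

# majority vote per row; ties -> lowest index in class_labels
vote_labels <- function(votes, class_labels) {
  apply(votes, 1L, function(v) {
    tab <- tabulate(match(v, class_labels), nbins = length(class_labels))
    class_labels[[which.max(tab)]]
  })
}

#' @export
print.kb_model <- function(x, ...) {
  cat("<kb_model> ", x$spec$family, " (", length(x$class_labels),
      " classes, D = ", x$fingerprint$d, ")\n", sep = "")
  invisible(x)
}

#' @method glance kb_model
#' @export
glance.kb_model <- function(x, ...) {
  tibble(
    family = x$spec$family,
    n_classes = length(x$class_labels),
    d = x$fingerprint$d,
    n_learners = x$spec$n_learners,
    seed = x$spec$seed
  )
}

#' Save or load a trained model
#'
#' Models are serialised with a format version and the feature fingerprint;
#' loading refuses files with a different format or version, and prediction
#' refuses feature matrices that do not match the fingerprint.
#'
#' @param model A `kb_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `kb_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "kb_model"))
  saveRDS(list(format = "kbalance_model", version = model$version,
               model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    kb_stop(paste0("cannot read model file '", path, "': ",
                   conditionMessage(e)),
            "kbalance_parse_error")
  })
  if (!is.list(obj) || !identical(obj$format, "kbalance_model")) {
    kb_stop(paste0("'", path, "' is not a kbalance model file"),
            "kbalance_parse_error")
  }
  if (!identical(obj$version, 1L)) {
    kb_stop(paste0("unsupported model format version: ", obj$version),
            "kbalance_version_error")
  }
  obj$model
}
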