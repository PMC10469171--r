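#' Alexander-Govern test of equal means under heteroscedasticity
#'
#' Compares group means without assuming equal variances: each group's t
#' statistic against the variance-weighted grand mean is normalised with the
#' Hill transformation and the sum of squared normalised statistics is
#' referred to a chi-square distribution with `k - 1` degrees of freedom.
#'
#' @param ... Two or more numeric vectors, or a single list of them.
#' @return List with `statistic`, `p_value`, `df`.
#' @examples
#' alexander_govern(rnorm(30), rnorm(30, 1))
#' @export
alexander_govern <- function(...) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1]])) groups <- groups[[1]]
  if (length(groups) < 2L) stop("need at least 2 groups")
  groups <- lapply(groups, function(g) g[is.finite(g)])
  n <- lengths(groups)
  if (any(n < 2L)) stop("each group needs n >= 2")
  v <- vapply(groups, stats::var, numeric(1))
  if (any(v == 0)) {
    stop("zero-variance group: ", which(v == 0)[1])
  }
  means <- vapply(groups, mean, numeric(1))
  se2 <- v / n
  w <- (1 / se2) / sum(1 / se2)
  grand <- sum(w * means)
  t_stat <- (means - grand) / sqrt(se2)
  nu <- n - 1
  a <- nu - 0.5
  b <- 48 * a^2
  cc <- sqrt(a * log1p(t_stat^2 / nu))
  z <- cc + (cc^3 + 3 * cc) / b -
    (4 * cc^7 + 33 * cc^5 + 240 * cc^3 + 855 * cc) /
    (10 * b^2 + 8 * b * cc^4 + 1000 * b)
  A <- sum(z^2)
  df <- length(groups) - 1L
  list(statistic = A, p_value = stats::pchisq(A, df, lower.tail = FALSE),
       df = df)
}

#' Pearson correlation between a criticality metric and performance
#'
#' Thin wrapper over [stats::cor.test()] returning the Pearson r and its
#' two-sided p-value; reported uncorrected (the exploratory convention) —
#' adjust across a family with [stats::p.adjust()] when several metrics are
#' screened.
#'
#' @param metric,performance Paired numeric vectors, `n >= 3`.
#' @return List with `r`, `p_value`, `n`.
#' @export
correlate_metric <- function(metric, performance) {
  if (length(metric) != length(performance)) stop("inputs must be paired")
  ok <- is.finite(metric) & is.finite(performance)
  metric <- metric[ok]
  performance <- performance[ok]
  if (length(metric) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(metric) == 0 || stats::sd(performance) == 0) {
    stop("constant input: correlation undefined")
  }
  ct <- stats::cor.test(metric, performance, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(metric))
}

feature_schema_columns <- function(schema) {
  schemas <- list(
    "4-metrics" = c("dcc", "br", "sc_error", "hm_ratio"),
    "3-criticality" = c("dcc", "br", "sc_error"),
    "dcc" = "dcc", "br" = "br", "sc_error" = "sc_error",
    "hm_ratio" = "hm_ratio")
  schema <- tolower(schema)
  if (!schema %in% names(schemas)) {
    stop("unknown schema '", schema, "'; use one of: ",
         paste(names(schemas), collapse = ", "))
  }
  schemas[[schema]]
}

build_features <- function(records, schema) {
  cols <- feature_schema_columns(schema)
  missing <- setdiff(cols, names(records))
  if (length(missing)) stop("records lack columns: ",
                            paste(missing, collapse = ", "))
  X <- as.matrix(records[, cols, drop = FALSE])
  ok <- stats::complete.cases(X)
  list(X = X[ok, , drop = FALSE], ok = ok)
}

#' Cross-validated binary classification of session state
#'
#' Predicts each session's condition from its criticality feature vector
#' with repeated stratified k-fold cross-validation. Features are
#' standardised using training-fold statistics only; held-out folds are
#' never touched during training.
#'
#' @param records data.frame of session records with a `condition` column
#'   (exactly 2 classes) and the metric columns of the chosen schema.
#' @param schema Feature schema: `"4-metrics"` (dcc, br, sc_error,
#'   hm_ratio), `"3-criticality"` (dcc, br, sc_error), or a single metric
#'   name.
#' @param classifier `"logistic"`, `"svm"` or `"random_forest"`.
#' @param folds Number of CV folds (default 5).
#' @param repeats Number of repeated fold assignments (default 10).
#' @param seed Optional seed for fold assignment (and forest bootstraps).
#' @return List with `mean_accuracy`, `fold_accuracy` (per repeat x fold),
#'   `classifier`, `schema`, `n`.
#' @export
classify_sessions <- function(records, schema = "4-metrics",
                              classifier = c("logistic", "svm",
                                             "random_forest"),
                              folds = 5, repeats = 10, seed = NULL) {
  classifier <- match.arg(classifier)
  feat <- build_features(records, schema)
  y <- factor(records$condition[feat$ok])
  X <- feat$X
  if (nlevels(y) != 2L) stop("need exactly 2 classes, got ", nlevels(y))
  if (length(y) < 10L) stop("need at least 10 records")
  if (!is.null(seed)) set.seed(seed)
  accs <- numeric(0)
  for (rep_i in seq_len(repeats)) {
    fold_id <- integer(length(y))
    for (lv in levels(y)) {
      idx <- which(y == lv)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2L || sum(!tr) == 0) next
      mu <- colMeans(X[tr, , drop = FALSE])
      sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      Xtr <- scale(X[tr, , drop = FALSE], mu, sdv)
      Xte <- scale(X[!tr, , drop = FALSE], mu, sdv)
      pred <- switch(classifier,
        logistic = {
          df_tr <- data.frame(Xtr, y = y[tr], check.names = FALSE)
          fit <- suppressWarnings(
            stats::glm(y ~ ., data = df_tr, family = stats::binomial()))
          p <- stats::predict(fit,
                              newdata = data.frame(Xte, check.names = FALSE),
                              type = "response")
          levels(y)[1 + (p > 0.5)]
        },
        svm = {
          fit <- e1071::svm(Xtr, y[tr], kernel = "radial")
          as.character(stats::predict(fit, Xte))
        },
        random_forest = {
          fit <- randomForest::randomForest(Xtr, y[tr], ntree = 200)
          as.character(stats::predict(fit, Xte))
        })
      accs <- c(accs, mean(pred == as.character(y[!tr])))
    }
  }
  list(mean_accuracy = mean(accs), fold_accuracy = accs,
       classifier = classifier, schema = schema, n = length(y))
}

#' Accuracy matrix over classifiers and feature schemas
#'
#' Convenience wrapper running [classify_sessions()] for every combination
#' of the three classifiers and the standard feature schemas, mirroring the
#' classifier-by-feature-vector layout of a prediction-accuracy table.
#'
#' @param records Session records data.frame (see [classify_sessions()]).
#' @param schemas Feature schemas to evaluate.
#' @param folds,repeats,seed Passed to [classify_sessions()].
#' @return data.frame with one row per classifier and one column per schema.
#' @export
classification_matrix <- function(records,
                                  schemas = c("4-metrics", "3-criticality",
                                              "dcc", "br", "sc_error",
                                              "hm_ratio"),
                                  folds = 5, repeats = 10, seed = NULL) {
  classifiers <- c("logistic", "svm", "random_forest")
  out <- matrix(NA_real_, nrow = length(classifiers),
                ncol = length(schemas),
                dimnames = list(classifiers, schemas))
  for (cl in classifiers) {
    for (sc in schemas) {
      out[cl, sc] <- classify_sessions(records, sc, cl, folds, repeats,
                                       seed = seed)$mean_accuracy
    }
  }
  as.data.frame(out)
}

#' Embed session feature vectors in 2-D by t-SNE
#'
#' Exact (dense) t-distributed stochastic neighbour embedding of the
#' standardised feature vectors, reporting the final Kullback-Leibler
#' divergence between the high-dimensional and embedded neighbour
#' distributions (lower = more faithful map).
#'
#' @param records Session records data.frame.
#' @param schema Feature schema (see [classify_sessions()]).
#' @param seed Optional seed for the embedding initialisation.
#' @param perplexity t-SNE perplexity; capped at `(n - 1) / 3`.
#' @param n_iter Gradient-descent iterations.
#' @return List with `coordinates` (n x 2 matrix) and `kl_divergence`.
#' @export
embed_sessions <- function(records, schema = "4-metrics", seed = NULL,
                           perplexity = 30, n_iter = 500) {
  feat <- build_features(records, schema)
  X <- feat$X
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 records to embed")
  if (!is.null(seed)) set.seed(seed)
  if (any(duplicated(X))) {
    warning("duplicated feature vectors: adding jitter before embedding")
    X <- X + matrix(stats::rnorm(length(X), sd = 1e-6), nrow = n)
  }
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  X <- scale(X, colMeans(X), sdv)
  res <- tsne_exact(X, perplexity = min(perplexity, (n - 1) / 3),
                    n_iter = n_iter)
  list(coordinates = res$Y, kl_divergence = res$kl)
}

# Exact O(n^2) t-SNE (perplexity-calibrated Gaussian affinities, Student-t
# low-dimensional kernel, momentum gradient descent with early exaggeration).
tsne_exact <- function(X, perplexity = 30, n_iter = 500, eta = 200) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { p[] <- 1 / length(p); sp <- 1 }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2
                                          else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2
                                 else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  exag <- 12
  for (iter in seq_len(n_iter)) {
    Pe <- if (iter <= 100) P * exag else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
    momentum <- if (iter <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- momentum * G - eta * gains * grad
    Y <- Y + G
    Y <- scale(Y, scale = FALSE)
  }
  num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
  diag(num) <- 0
  Q <- pmax(num / sum(num), 1e-12)
  list(Y = Y, kl = sum(P * log(P / Q)))
}
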