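#' SIMCA training set for one chemical class
#'
#' Rows are normalized EI spectra (relative intensities, base peak 100) of
#' the compounds known to belong to one chemical class; columns are the
#' integer m/z bins.
#'
#' @param class_name Class label (e.g. "sugar phosphate").
#' @param X Numeric matrix, m compounds x p m/z bins.
#' @param compound_names Optional character vector of row names.
#' @param mz_min First m/z bin of the columns.
#' @return An object of class `simca_training_set`.
#' @export
training_set <- function(class_name, X, compound_names = NULL, mz_min = 85L) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) {
    stop(sprintf("class '%s': need at least 3 training spectra, got %d",
                 class_name, nrow(X)), call. = FALSE)
  }
  if (any(rowSums(abs(X)) == 0)) {
    stop(sprintf("class '%s': all-zero training spectrum", class_name),
         call. = FALSE)
  }
  if (is.null(compound_names)) {
    compound_names <- sprintf("%s_%02d", gsub("\\s+", "_", class_name),
                              seq_len(nrow(X)))
  }
  stopifnot(length(compound_names) == nrow(X))
  rownames(X) <- compound_names
  structure(list(class_name = as.character(class_name), X = X,
                 compound_names = as.character(compound_names),
                 mz_min = as.integer(mz_min)),
            class = "simca_training_set")
}

# residual standard deviation from a training residual matrix E (m x p):
# s0 = sqrt(SSE / ((m - r - 1) * (p - r)))
rsd_from_residuals <- function(E, m, r, p) {
  sqrt(sum(E^2) / ((m - r - 1) * (p - r)))
}

#' Fit one SIMCA class model by principal-component analysis
#'
#' The class training matrix is mean-centered (no autoscaling: all variables
#' share intensity units) and decomposed by SVD; the top `r` right singular
#' directions span the class subspace. The training residual standard
#' deviation is `s0 = sqrt(SSE / ((m - r - 1)(p - r)))`, the class's
#' within-model noise scale against which new objects are tested.
#'
#' @param train A `simca_training_set`.
#' @param r Number of retained components, or `"auto"` to choose by
#'   leave-one-out cross-validation ([choose_components_cv()]).
#' @param r_max Upper bound for the automatic choice; capped at
#'   `min(5, m - 2)`.
#' @return An object of class `simca_model` with fields `class_name`,
#'   `mean`, `loadings` (p x r, orthonormal), `r`, `s0`, `m`, `p`.
#' @export
fit_class_model <- function(train, r = "auto", r_max = 5L) {
  stopifnot(inherits(train, "simca_training_set"))
  X <- train$X
  m <- nrow(X)
  p <- ncol(X)
  if (identical(r, "auto")) {
    r <- choose_components_cv(train, r_max = min(r_max, m - 2L))
  }
  r <- as.integer(r)
  if (r < 1L) stop("at least one component must be retained", call. = FALSE)
  if (m < r + 2L) {
    stop(sprintf(
      "class '%s': m >= r + 2 required for the residual df (m - r - 1 >= 1); m = %d, r = %d",
      train$class_name, m, r), call. = FALSE)
  }
  if (r > p) stop("r cannot exceed the number of variables", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0L, nv = r)
  V <- sv$v
  scores <- Xc %*% V
  E <- Xc - scores %*% t(V)
  structure(list(class_name = train$class_name, mean = mu, loadings = V,
                 r = r, s0 = rsd_from_residuals(E, m, r, p),
                 m = m, p = p, singular_values = sv$d[seq_len(r)],
                 mz_min = train$mz_min),
            class = "simca_model")
}

#' @export
print.simca_model <- function(x, ...) {
  cat(sprintf("<simca_model> class '%s': m = %d, p = %d, r = %d, s0 = %.4g\n",
              x$class_name, x$m, x$p, x$r, x$s0))
  invisible(x)
}

#' Training residual standard deviation of a fitted class model
#'
#' Recomputes `s0 = sqrt(SSE / ((m - r - 1)(p - r)))` from the training set
#' and the model.
#'
#' @param train The `simca_training_set` the model was fitted on.
#' @param model The fitted `simca_model`.
#' @return The residual standard deviation s0.
#' @export
residual_sd_training <- function(train, model) {
  stopifnot(inherits(train, "simca_training_set"),
            inherits(model, "simca_model"))
  Xc <- sweep(train$X, 2L, model$mean)
  E <- Xc - (Xc %*% model$loadings) %*% t(model$loadings)
  rsd_from_residuals(E, model$m, model$r, model$p)
}

#' Project a new spectrum onto a class model
#'
#' The centered object is projected onto the class subspace; the residual is
#' the out-of-subspace part, summarized as
#' `s_j = sqrt(sum(residual^2) / (p - r))`, a Euclidean distance to the
#' class model corrected for its degrees of freedom.
#'
#' @param x Numeric vector of length p (a normalized spectrum).
#' @param model A `simca_model`.
#' @return List with `scores` (length r), `residual` (length p) and `s_j`.
#' @export
project_and_residual <- function(x, model) {
  stopifnot(inherits(model, "simca_model"))
  x <- as.numeric(x)
  if (length(x) != model$p) {
    stop(sprintf("object has %d variables but model '%s' expects %d",
                 length(x), model$class_name, model$p), call. = FALSE)
  }
  if (any(!is.finite(x))) stop("object must be finite", call. = FALSE)
  centered <- x - model$mean
  scores <- drop(crossprod(model$loadings, centered))
  residual <- centered - drop(model$loadings %*% scores)
  list(scores = scores, residual = residual,
       s_j = sqrt(sum(residual^2) / (model$p - model$r)))
}

#' F-test for class membership
#'
#' Compares an object's residual standard deviation `s_j` with the class's
#' training value `s0` via `F = s_j^2 / s0^2`. The default degrees of
#' freedom are `(m - r - 1)` and `(m - r - 1)^2`; the alternative
#' `"classical"` convention uses `(p - r)` and `(p - r)(m - r - 1)`. The
#' object is a member when the upper-tail p-value exceeds `alpha` (residual
#' variances not significantly different).
#'
#' @param s_j Object residual SD from [project_and_residual()].
#' @param s0 Training residual SD (> 0).
#' @param m,r,p Training size, retained components, variable count.
#' @param alpha Significance level in (0, 1).
#' @param df_convention `"paper"` (default) or `"classical"`.
#' @return List with `F`, `p_value`, `member`, `df1`, `df2`.
#' @export
f_test_membership <- function(s_j, s0, m, r, p = NULL, alpha = 0.05,
                              df_convention = c("paper", "classical")) {
  df_convention <- match.arg(df_convention)
  if (!is.finite(s0) || s0 <= 0) {
    stop("degenerate class model: s0 == 0; add training objects or noise so the residual variance is estimable",
         call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (df_convention == "paper") {
    df1 <- m - r - 1
    df2 <- (m - r - 1)^2
  } else {
    if (is.null(p)) stop("classical df convention needs p", call. = FALSE)
    df1 <- p - r
    df2 <- (p - r) * (m - r - 1)
  }
  if (df1 < 1 || df2 < 1) {
    stop("non-positive degrees of freedom; increase m or decrease r",
         call. = FALSE)
  }
  Fval <- (s_j / s0)^2
  pval <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
  list(F = Fval, p_value = pval, member = pval > alpha, df1 = df1, df2 = df2)
}

#' Classify a spectrum against all class models
#'
#' The membership F-test is run against every class. With no accepting
#' class the object is "unknown"; with several, the class with the largest
#' p-value (smallest relative residual) wins and the multi-class flag is set.
#'
#' @param x Numeric vector of length p (normalized spectrum).
#' @param models List of `simca_model` objects sharing p.
#' @param alpha Significance level.
#' @param df_convention Passed to [f_test_membership()].
#' @return List with `per_class` (data.frame: class, s_j, F, p_value,
#'   member), `final_label` (class name or "unknown"), `multi_class`.
#' @export
classify_spectrum <- function(x, models, alpha = 0.05,
                              df_convention = c("paper", "classical")) {
  df_convention <- match.arg(df_convention)
  if (length(models) < 1L) stop("need at least one class model", call. = FALSE)
  ps <- vapply(models, function(mod) mod$p, numeric(1))
  if (length(unique(ps)) != 1L) {
    bad <- models[[which(ps != ps[1])[1]]]$class_name
    stop(sprintf("model '%s' has a different variable count", bad),
         call. = FALSE)
  }
  per <- do.call(rbind, lapply(models, function(mod) {
    pr <- project_and_residual(x, mod)
    ft <- f_test_membership(pr$s_j, mod$s0, mod$m, mod$r, mod$p,
                            alpha = alpha, df_convention = df_convention)
    data.frame(class = mod$class_name, s_j = pr$s_j, F = ft$F,
               p_value = ft$p_value, member = ft$member,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  members <- which(per$member)
  final <- if (length(members) == 0L) "unknown"
           else per$class[members[which.max(per$p_value[members])]]
  list(per_class = per, final_label = final,
       multi_class = length(members) >= 2L)
}

#' Choose the number of components by leave-one-out cross-validation
#'
#' For each candidate r, every training spectrum is held out in turn, the
#' PCA refitted on the rest, and the held-out spectrum's squared residual to
#' the r-component subspace accumulated (PRESS). PRESS values are compared
#' per residual degree of freedom (PRESS / (p - r), matching the residual-SD
#' conventions used throughout), which cancels the spurious ~1/p gain every
#' extra component earns by absorbing noise. The smallest r within 1% of the
#' minimum is returned (parsimony). The zero-component model (mean only)
#' competes as a baseline, so structureless data fall back to it, but at
#' least one component is always retained.
#'
#' @param train A `simca_training_set`.
#' @param r_max Largest r to consider (`<= m - 2`).
#' @return The chosen number of components (>= 1).
#' @export
choose_components_cv <- function(train, r_max = 5L) {
  stopifnot(inherits(train, "simca_training_set"))
  X <- train$X
  m <- nrow(X)
  r_max <- min(as.integer(r_max), m - 2L)
  if (r_max < 1L) stop("too few training objects for cross-validation",
                       call. = FALSE)
  press <- numeric(r_max + 1L)  # press[1] is the zero-component baseline
  for (k in seq_len(m)) {
    Xk <- X[-k, , drop = FALSE]
    mu <- colMeans(Xk)
    sv <- svd(sweep(Xk, 2L, mu), nu = 0L, nv = min(r_max, nrow(Xk)))
    centered <- X[k, ] - mu
    sc <- drop(crossprod(sv$v, centered))
    # residual SSE decreases by sc[r]^2 as each component is added
    total <- sum(centered^2)
    press[1] <- press[1] + total
    for (r in seq_len(r_max)) {
      used <- seq_len(min(r, length(sc)))
      press[r + 1L] <- press[r + 1L] + total - sum(sc[used]^2)
    }
  }
  # parsimony on the df-corrected criterion: smallest r within 1% of the
  # minimum; the absolute term guards against round-off when the residual is
  # numerically zero; r = 0 (structureless data) is floored to one component
  p <- ncol(X)
  crit <- press / (p - 0:r_max)
  threshold <- min(crit) + 0.01 * abs(min(crit)) + 1e-12 * crit[1]
  max(1L, which(crit <= threshold)[1] - 1L)
}

#' Interclass distance between two SIMCA class models
#'
#' `s_qr` is the interclass residual of class q's training objects projected
#' into class r's model, with `m_q (p - r_r)` degrees of freedom; `s_qq` is
#' class q's own residual recomputed with `m_q (p - r_q)` degrees of
#' freedom. The distance is
#' `D = max(0, sqrt((s12^2 + s21^2) / (s11^2 + s22^2)) - 1)`:
#' zero for a model against itself, symmetric, and values above one indicate
#' genuinely separated classes.
#'
#' @param model1,model2 Fitted `simca_model` objects.
#' @param train1,train2 Their training sets.
#' @return The interclass distance D (>= 0).
#' @export
interclass_distance <- function(model1, model2, train1, train2) {
  stopifnot(inherits(model1, "simca_model"), inherits(model2, "simca_model"),
            inherits(train1, "simca_training_set"),
            inherits(train2, "simca_training_set"))
  if (model1$p != model2$p) stop("models must share p", call. = FALSE)
  sse_into <- function(train, model) {
    Xc <- sweep(train$X, 2L, model$mean)
    E <- Xc - (Xc %*% model$loadings) %*% t(model$loadings)
    sum(E^2)
  }
  p <- model1$p
  s11_sq <- sse_into(train1, model1) / (nrow(train1$X) * (p - model1$r))
  s22_sq <- sse_into(train2, model2) / (nrow(train2$X) * (p - model2$r))
  if (s11_sq + s22_sq <= 0) {
    stop("degenerate class models: both own-class residuals are zero",
         call. = FALSE)
  }
  s12_sq <- sse_into(train1, model2) / (nrow(train1$X) * (p - model2$r))
  s21_sq <- sse_into(train2, model1) / (nrow(train2$X) * (p - model1$r))
  max(0, sqrt((s12_sq + s21_sq) / (s11_sq + s22_sq)) - 1)
}

#' Class-characteristic m/z bins of a model
#'
#' Ranks the m/z bins by their absolute loading magnitude on the retained
#' components, weighted by each component's explained variance; these are
#' the fragments that characterize the chemical class (e.g. m/z 299 for
#' sugar phosphates).
#'
#' @param model A fitted `simca_model`.
#' @param k How many bins to return.
#' @return Integer vector of m/z values, most important first.
#' @export
important_mz <- function(model, k = 4L) {
  stopifnot(inherits(model, "simca_model"))
  k <- as.integer(k)
  if (k > model$p) {
    warning(sprintf("k capped at p = %d variables", model$p))
    k <- model$p
  }
  lambda <- model$singular_values^2 / (model$m - 1)
  score <- sqrt(drop(model$loadings^2 %*% lambda))
  ord <- order(score, decreasing = TRUE)[seq_len(k)]
  model$mz_min + ord - 1L
}

#' Leave-one-out cross-validation of a set of class models
#'
#' Each training spectrum is held out in turn, every class model refitted
#' without it, and the held-out spectrum classified. Returns a confusion
#' matrix of final labels by true class, with an extra "unknown" column for
#' objects accepted by no class.
#'
#' @param all_training List of `simca_training_set` objects (>= 2 classes).
#' @param alpha Significance level for membership.
#' @param r Components per class: `"auto"` (cross-validated at each refit)
#'   or a fixed integer.
#' @param df_convention Passed to [f_test_membership()].
#' @return Integer matrix: rows = true classes, columns = predicted classes
#'   plus "unknown"; row sums equal class sizes.
#' @export
cross_validate_models <- function(all_training, alpha = 0.05, r = "auto",
                                  df_convention = c("paper", "classical")) {
  df_convention <- match.arg(df_convention)
  if (length(all_training) < 1L) {
    stop("need at least one class for cross-validation", call. = FALSE)
  }
  classes <- vapply(all_training, function(tr) tr$class_name, character(1))
  conf <- matrix(0L, nrow = length(classes), ncol = length(classes) + 1L,
                 dimnames = list(classes, c(classes, "unknown")))
  full_models <- lapply(all_training, fit_class_model, r = r)
  for (ci in seq_along(all_training)) {
    tr <- all_training[[ci]]
    for (k in seq_len(nrow(tr$X))) {
      if (nrow(tr$X) - 1L < 3L) {
        stop(sprintf("class '%s' would shrink below 3 objects during leave-one-out",
                     tr$class_name), call. = FALSE)
      }
      loo_train <- training_set(tr$class_name, tr$X[-k, , drop = FALSE],
                                tr$compound_names[-k], tr$mz_min)
      models <- full_models
      models[[ci]] <- fit_class_model(loo_train, r = r)
      res <- classify_spectrum(tr$X[k, ], models, alpha = alpha,
                               df_convention = df_convention)
      conf[ci, res$final_label] <- conf[ci, res$final_label] + 1L
    }
  }
  conf
}

#' Serialize fitted class models to JSON
#'
#' @param models List of `simca_model` objects.
#' @param path Output path for the JSON document.
#' @return The path, invisibly.
#' @export
write_class_models <- function(models, path) {
  payload <- lapply(models, function(mod) {
    list(class_name = mod$class_name, mean = mod$mean,
         loadings = mod$loadings, r = mod$r, s0 = mod$s0, m = mod$m,
         p = mod$p, singular_values = mod$singular_values,
         mz_min = mod$mz_min)
  })
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read class models serialized by [write_class_models()]
#'
#' @param path Path to the JSON document.
#' @return List of `simca_model` objects.
#' @export
read_class_models <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("model file not found: %s", path), call. = FALSE)
  }
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(mod) {
    r <- as.integer(mod$r)
    L <- mod$loadings
    # a p x 1 matrix serializes as a plain vector; p x r (r > 1) as a list of rows
    L <- if (is.list(L)) do.call(rbind, lapply(L, as.numeric))
         else matrix(as.numeric(L), ncol = r)
    structure(list(class_name = mod$class_name,
                   mean = as.numeric(mod$mean),
                   loadings = L,
                   r = r, s0 = as.numeric(mod$s0),
                   m = as.integer(mod$m), p = as.integer(mod$p),
                   singular_values = as.numeric(mod$singular_values),
                   mz_min = as.integer(mod$mz_min)),
              class = "simca_model")
  })
}
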