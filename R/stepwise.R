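feature_columns <- function(table) {
  intersect(texture_feature_names, names(table))
}

response_vector <- function(table) {
  lab <- table$label
  if (!all(lab %in% c("E", "NE")))
    stop("labels must be 'E' or 'NE' (E is the positive class)", call. = FALSE)
  as.integer(lab == "E")
}

#' Maximum-likelihood logistic fit on a feature subset
#'
#' Fits P(E | x) by binomial GLM with a linear logit in the given
#' features on their raw scale. The problem is convex, so the fit is
#' deterministic given the data. Perfect separation is detected and
#' flagged with a warning rather than an error; a rank-deficient design
#' (e.g. a constant feature) is an error.
#'
#' @param table feature table with a `label` column ("E" = positive).
#' @param features character vector of feature columns; empty for the
#'   intercept-only model.
#' @return A list with `features`, `coefficients`, `loglik`, `aic`,
#'   `wald` (estimate / se / z / p per term), `separation`, and the
#'   underlying `fit`.
#' @export
fit_logistic <- function(table, features = character(0)) {
  y <- response_vector(table)
  if (length(unique(y)) < 2L)
    stop("both classes must be present to fit", call. = FALSE)
  if (length(features)) {
    miss <- setdiff(features, names(table))
    if (length(miss))
      stop("features not in table: ", paste(miss, collapse = ", "), call. = FALSE)
    dat <- table[features]
    X <- cbind(1, as.matrix(dat))
    if (qr(X)$rank < ncol(X))
      stop("singular design: the selected features are collinear or constant",
           call. = FALSE)
    dat$.y <- y
    form <- stats::reformulate(sprintf("`%s`", features), response = ".y")
  } else {
    dat <- data.frame(.y = y)
    form <- .y ~ 1
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (length(features) && !separation &&
      (any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)))
    separation <- TRUE
  if (separation)
    warning("perfect or quasi-perfect separation detected; coefficients are unstable",
            call. = FALSE)
  sm <- summary(fit)$coefficients
  rn <- gsub("`", "", rownames(sm))
  wald <- data.frame(term = rn, estimate = sm[, 1], se = sm[, 2],
                     z = sm[, 3], p = sm[, 4], row.names = NULL,
                     stringsAsFactors = FALSE)
  cf <- stats::coef(fit)
  names(cf) <- rn
  list(features = features, coefficients = cf,
       loglik = as.numeric(stats::logLik(fit)), aic = stats::AIC(fit),
       wald = wald, separation = separation, fit = fit)
}

# p-value of one term inside a fitted model. Under (quasi-)separation the
# Wald statistic collapses toward zero (Hauck-Donner effect), so the
# likelihood-ratio test is used instead whenever separation is flagged.
term_p <- function(model, feature, table, entry_test) {
  if (entry_test == "wald" && !model$separation)
    return(model$wald$p[model$wald$term == feature])
  base <- suppressWarnings(fit_logistic(table, setdiff(model$features, feature)))
  stats::pchisq(2 * (model$loglik - base$loglik), df = 1, lower.tail = FALSE)
}

#' Forward stepwise logistic regression with an AIC guard
#'
#' Iterative variable selection discriminating expected from non-expected
#' ROIs. At each step the candidate whose term test gives the smallest
#' p-value below `p_enter` is added ("lowest p-value in"); then any
#' included term whose p-value exceeds `p_remove` is dropped, largest
#' first. Selection stops when no candidate qualifies or when the best
#' addition would raise the Akaike information criterion (the
#' overfitting guard). Entry/removal tests are Wald by default; a
#' likelihood-ratio entry test is available. Ties in candidate p-values
#' break lexicographically by feature name for reproducibility.
#'
#' @param table feature table with `label` and feature columns.
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.15); must be
#'   >= `p_enter`.
#' @param features candidate features; default all feature columns
#'   present.
#' @param entry_test "wald" (default) or "lr".
#' @param aic_guard refuse an addition that raises AIC (default TRUE).
#' @param max_steps cap on accepted additions; default unlimited.
#' @return An object of class `stepwise_model`: `selected_features` (in
#'   entry order, minus removals), `coefficients`, `wald_stats`,
#'   `aic_trace`, `step_log`, `loglik`, `aic`, `separation`.
#' @export
stepwise_select <- function(table, p_enter = 0.05, p_remove = 0.15,
                            features = feature_columns(table),
                            entry_test = c("wald", "lr"),
                            aic_guard = TRUE, max_steps = Inf) {
  entry_test <- match.arg(entry_test)
  if (!nrow(table)) stop("empty feature table", call. = FALSE)
  if (p_enter > p_remove)
    stop("`p_enter` must be <= `p_remove` (else selection can cycle)", call. = FALSE)
  if (anyNA(table[features])) stop("feature table contains missing values", call. = FALSE)
  features <- sort(features)   # lexicographic candidate order (tie-break)

  current <- character(0)
  cur_fit <- fit_logistic(table, current)
  aic_trace <- cur_fit$aic
  log_rows <- list()
  n_added <- 0L

  repeat {
    if (n_added >= max_steps) break
    candidates <- setdiff(features, current)
    if (!length(candidates)) break

    best <- NULL
    for (f in candidates) {
      fit_f <- tryCatch(suppressWarnings(fit_logistic(table, c(current, f))),
                        error = function(e) NULL)
      if (is.null(fit_f)) next
      p <- term_p(fit_f, f, table, entry_test)
      if (length(p) == 1 && is.finite(p) && p < p_enter &&
          (is.null(best) || p < best$p))
        best <- list(feature = f, p = p, fit = fit_f)
    }
    if (is.null(best)) break
    if (aic_guard && best$fit$aic > cur_fit$aic) {
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(step = length(log_rows) + 1L, action = "stop_aic",
                   feature = best$feature, p = best$p, aic = best$fit$aic,
                   stringsAsFactors = FALSE)
      break
    }

    current <- c(current, best$feature)
    cur_fit <- best$fit
    n_added <- n_added + 1L
    aic_trace <- c(aic_trace, cur_fit$aic)
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(step = length(log_rows) + 1L, action = "add",
                 feature = best$feature, p = best$p, aic = cur_fit$aic,
                 stringsAsFactors = FALSE)

    # backward pass: drop included terms whose p exceeds p_remove
    repeat {
      ps <- vapply(current, function(f) term_p(cur_fit, f, table, "wald"),
                   numeric(1))
      bad <- data.frame(term = current, p = ps)[ps > p_remove, , drop = FALSE]
      if (!nrow(bad)) break
      drop <- bad$term[order(-bad$p, bad$term)][1]
      current <- setdiff(current, drop)
      cur_fit <- suppressWarnings(fit_logistic(table, current))
      aic_trace <- c(aic_trace, cur_fit$aic)
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(step = length(log_rows) + 1L, action = "remove",
                   feature = drop, p = max(bad$p), aic = cur_fit$aic,
                   stringsAsFactors = FALSE)
    }
  }

  step_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(step = integer(0), action = character(0), feature = character(0),
               p = numeric(0), aic = numeric(0))
  structure(list(selected_features = current,
                 coefficients = cur_fit$coefficients,
                 wald_stats = cur_fit$wald, aic_trace = aic_trace,
                 step_log = step_log, loglik = cur_fit$loglik,
                 aic = cur_fit$aic, separation = cur_fit$separation,
                 p_enter = p_enter, p_remove = p_remove,
                 entry_test = entry_test),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat("<stepwise_model> ", length(x$selected_features), " feature(s): ",
      paste(x$selected_features, collapse = ", "), "\n", sep = "")
  cat("  AIC ", round(x$aic, 2), ", log-likelihood ", round(x$loglik, 2), "\n", sep = "")
  invisible(x)
}

#' Predicted probability of true (expected) activity
#'
#' Inverse-logit of the fitted linear predictor for new ROI rows.
#'
#' @param object a `stepwise_model`.
#' @param newdata data.frame containing every selected feature column.
#' @param ... unused.
#' @return Numeric vector of P(E) in (0, 1).
#' @export
predict.stepwise_model <- function(object, newdata, ...) {
  miss <- setdiff(object$selected_features, names(newdata))
  if (length(miss))
    stop("newdata is missing selected feature column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  eta <- rep(object$coefficients[["(Intercept)"]], nrow(newdata))
  for (f in object$selected_features)
    eta <- eta + object$coefficients[[f]] * newdata[[f]]
  stats::plogis(eta)
}

#' Odds ratios of the selected terms
#'
#' @param model a `stepwise_model`.
#' @param alpha significance level for the Wald flag; default 0.05.
#' @return data.frame: `feature`, `odds_ratio` (= exp(coefficient)),
#'   `wald_p`, `significant`.
#' @export
odds_ratios <- function(model, alpha = 0.05) {
  w <- model$wald_stats[model$wald_stats$term %in% model$selected_features, ,
                        drop = FALSE]
  data.frame(feature = w$term, odds_ratio = exp(w$estimate), wald_p = w$p,
             significant = w$p < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Serialize a stepwise model as JSON
#' @param model a `stepwise_model`.
#' @param path output path.
#' @export
write_stepwise_model <- function(model, path) {
  out <- model[c("selected_features", "aic_trace", "loglik",
                 "aic", "p_enter", "p_remove", "entry_test")]
  out$coefficients <- as.list(model$coefficients)
  out$wald_stats <- model$wald_stats
  out$step_log <- model$step_log
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
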