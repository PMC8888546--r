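#' Rank-based inverse-normal transform
#'
#' Maps a variable to normal quantiles: `y_i = qnorm((r_i - c) / (n - 2c + 1))`
#' with average ranks for ties and the Blom offset `c = 3/8` (the standard
#' choice in statistical genetics; for c = 3/8 the denominator is n + 1/4).
#' Missing values propagate; n counts non-missing values.
#'
#' @param x numeric vector with at least two distinct non-missing values.
#' @param offset rank offset c (default 3/8).
#' @return transformed vector, NA preserved.
#' @export
inverse_normal_transform <- function(x, offset = 3 / 8) {
  obs <- !is.na(x)
  if (sum(obs) < 2L) stop("need >= 2 non-missing values")
  if (length(unique(x[obs])) < 2L) stop("degenerate input: all values equal")
  r <- rank(x[obs], ties.method = "average")
  n <- sum(obs)
  y <- x
  y[obs] <- qnorm((r - offset) / (n - 2 * offset + 1))
  y
}

ols_fit <- function(y, X) {
  # X: data.frame of predictors (no intercept column); returns lm fit on
  # complete cases with intercept
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- lm(.y ~ ., data = df)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  fit
}

r_squared <- function(y, X) {
  if (is.null(X) || ncol(as.data.frame(X)) == 0L) return(0)
  summary(ols_fit(y, as.data.frame(X)))$r.squared
}

#' Test one topic loading against one PRS tranche
#'
#' Ordinary least squares of the inverse-normal-transformed topic loading on
#' the PRS plus covariates (conventionally age, sex and the first five genetic
#' principal components), on complete cases. Reports the PRS coefficient
#' (per-SD effect when scores are standardized), its two-sided p-value, the
#' semi-partial R-squared `sr2 = R2_full - R2_without_PRS` (the PRS's unique
#' variance share; multiplied by 100 this is the conventional
#' "percent variance explained"), and the partial R-squared
#' `sr2 / (1 - R2_without_PRS)`.
#'
#' @param theta_topic per-subject topic loading (raw; transformed internally
#'   unless `transform = FALSE`).
#' @param prs per-subject PRS values.
#' @param covars optional data.frame of covariates.
#' @param topic,trait,tranche labels carried into the result.
#' @param transform apply [inverse_normal_transform()] to the outcome.
#' @return object of class `association_result` (also a one-row data.frame):
#'   topic, trait, tranche, n, beta_hat, se, t, p, sr2, partial_r2.
#' @export
fit_topic_prs <- function(theta_topic, prs, covars = NULL, topic = NA,
                          trait = NA_character_, tranche = NA_character_,
                          transform = TRUE) {
  n_in <- length(theta_topic)
  stopifnot(length(prs) == n_in)
  if (!is.null(covars)) {
    covars <- as.data.frame(covars)
    stopifnot(nrow(covars) == n_in)
  }
  cc <- !is.na(theta_topic) & !is.na(prs)
  if (!is.null(covars)) cc <- cc & complete.cases(covars)
  n <- sum(cc)
  n_pred <- 1L + if (is.null(covars)) 0L else ncol(covars)
  if (n < n_pred + 2L) stop("too few complete cases for the model")
  y <- if (transform) inverse_normal_transform(theta_topic[cc]) else theta_topic[cc]
  X_full <- data.frame(PRS = prs[cc])
  if (!is.null(covars)) X_full <- cbind(X_full, covars[cc, , drop = FALSE])
  fit <- ols_fit(y, X_full)
  sm <- summary(fit)$coefficients
  r2_full <- summary(ols_fit(y, X_full))$r.squared
  r2_red <- r_squared(y, if (is.null(covars)) NULL else covars[cc, , drop = FALSE])
  sr2 <- max(0, r2_full - r2_red)
  res <- data.frame(topic = topic, trait = trait, tranche = tranche, n = n,
                    beta_hat = sm["PRS", 1], se = sm["PRS", 2],
                    t = sm["PRS", 3], p = sm["PRS", 4],
                    sr2 = sr2, partial_r2 = sr2 / (1 - r2_red))
  class(res) <- c("association_result", class(res))
  attr(res, "fit") <- fit
  res
}

#' Nested-model comparison by F-test (ANOVA)
#'
#' Compares the fit of a full model against a nested reduced model on the same
#' rows: `F = [(RSS_red - RSS_full) / (df_red - df_full)] / [RSS_full /
#' df_full]`, with the p-value from the F distribution. Used to ask whether
#' adding a second PRS improves the prediction of a topic.
#'
#' @param y outcome vector (already transformed if desired).
#' @param full data.frame of full-model predictors.
#' @param reduced data.frame of reduced-model predictors; its columns must be
#'   a strict subset of `full`'s.
#' @return object of class `model_comparison`: F, df1, df2, p_anova, r2_full,
#'   r2_reduced, full_terms, reduced_terms.
#' @export
compare_models <- function(y, full, reduced) {
  full <- as.data.frame(full)
  reduced <- if (is.null(reduced)) data.frame(row.names = seq_along(y))
             else as.data.frame(reduced)
  if (!all(names(reduced) %in% names(full))) {
    stop("models are not nested: reduced has terms absent from full")
  }
  if (ncol(reduced) >= ncol(full)) stop("reduced model must be a strict sub-model")
  cc <- !is.na(y) & complete.cases(full)
  y <- y[cc]
  full <- full[cc, , drop = FALSE]
  reduced <- reduced[cc, , drop = FALSE]
  fit_full <- ols_fit(y, full)
  rss_full <- sum(residuals(fit_full)^2)
  df_full <- fit_full$df.residual
  if (ncol(reduced)) {
    fit_red <- ols_fit(y, reduced)
    rss_red <- sum(residuals(fit_red)^2)
    df_red <- fit_red$df.residual
    r2_red <- summary(fit_red)$r.squared
  } else {
    rss_red <- sum((y - mean(y))^2)
    df_red <- length(y) - 1L
    r2_red <- 0
  }
  Fstat <- ((rss_red - rss_full) / (df_red - df_full)) / (rss_full / df_full)
  structure(list(F = Fstat, df1 = df_red - df_full, df2 = df_full,
                 p_anova = pf(Fstat, df_red - df_full, df_full, lower.tail = FALSE),
                 r2_full = summary(fit_full)$r.squared, r2_reduced = r2_red,
                 full_terms = names(full), reduced_terms = names(reduced)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("model_comparison: F(%d, %d) = %.4g, p = %.4g (R2 %.4f -> %.4f)\n",
              x$df1, x$df2, x$F, x$p_anova, x$r2_reduced, x$r2_full))
  invisible(x)
}

#' Semi-partial and partial variance decomposition
#'
#' For each predictor of interest j in an OLS model,
#' `sr2_j = R2_full - R2_drop_j` (its unique variance contribution; 100 * sr2
#' is the conventional percent-variance-explained) and
#' `partial_r2_j = sr2_j / (1 - R2_drop_j)`.
#'
#' @param y outcome vector.
#' @param predictors data.frame of all model predictors.
#' @param of_interest predictor names to decompose (default: all).
#' @return data.frame: predictor, sr2, partial_r2, pct_variance; attribute
#'   `r2_full`.
#' @export
variance_decomposition <- function(y, predictors, of_interest = names(predictors)) {
  predictors <- as.data.frame(predictors)
  stopifnot(all(of_interest %in% names(predictors)))
  cc <- !is.na(y) & complete.cases(predictors)
  y <- y[cc]
  predictors <- predictors[cc, , drop = FALSE]
  r2_full <- r_squared(y, predictors)
  rows <- lapply(of_interest, function(nm) {
    rest <- predictors[setdiff(names(predictors), nm)]
    r2_drop <- r_squared(y, if (ncol(rest)) rest else NULL)
    sr2 <- max(0, r2_full - r2_drop)
    data.frame(predictor = nm, sr2 = sr2,
               partial_r2 = sr2 / (1 - r2_drop), pct_variance = 100 * sr2)
  })
  out <- do.call(rbind, rows)
  attr(out, "r2_full") <- r2_full
  out
}

#' Scan all topic x trait x tranche associations
#'
#' Runs [fit_topic_prs()] for every topic loading against every tranche of
#' every trait's PRS profile, with shared covariates, aligning subjects by
#' identifier. Emits a long-format table annotated with Bonferroni and
#' Benjamini-Hochberg adjusted p-values (nominal p is the primary column, the
#' adjustments are informational) and, per trait, a topic x tranche matrix of
#' -log10 p ready for a heatmap. Topics can be excluded from the scan (e.g. a
#' topic judged an artefact, such as one dominated by maternal substance use).
#'
#' @param theta document-topic matrix (subjects x topics, rownames = ids).
#' @param profiles named list of [score_prs()] profiles, one per trait.
#' @param covars optional covariate data.frame with rownames = subject ids.
#' @param exclude_topics integer topic indices to drop from the scan.
#' @return list with `table` (long data.frame) and `neglog10p` (named list of
#'   topic x tranche matrices).
#' @export
association_scan <- function(theta, profiles, covars = NULL,
                             exclude_topics = NULL) {
  stopifnot(is.matrix(theta), length(profiles) >= 1L)
  if (is.null(names(profiles))) {
    names(profiles) <- vapply(profiles, function(p) p$trait, character(1))
  }
  ids <- rownames(theta)
  if (is.null(ids)) stop("theta must have subject ids as rownames")
  for (tr in names(profiles)) {
    pid <- rownames(profiles[[tr]]$scores)
    if (!setequal(pid, ids)) {
      off <- union(setdiff(ids, pid), setdiff(pid, ids))
      stop("subject-id mismatch with trait '", tr, "': ",
           paste(head(off, 5), collapse = ", "))
    }
  }
  if (!is.null(covars)) {
    covars <- as.data.frame(covars)
    if (!is.null(rownames(covars)) && !all(rownames(covars) == as.character(seq_len(nrow(covars))))) {
      if (!setequal(rownames(covars), ids)) {
        stop("subject-id mismatch between theta and covariates")
      }
      covars <- covars[ids, , drop = FALSE]
    } else {
      stopifnot(nrow(covars) == length(ids))
    }
  }
  topics <- setdiff(seq_len(ncol(theta)), exclude_topics)
  rows <- list()
  for (trait in names(profiles)) {
    sc <- profiles[[trait]]$scores[ids, , drop = FALSE]
    for (k in topics) {
      for (tranche in colnames(sc)) {
        s <- sc[, tranche]
        rows[[length(rows) + 1L]] <-
          if (tranche %in% profiles[[trait]]$degenerate || sd(s, na.rm = TRUE) == 0) {
            # empty or constant tranche: no testable score
            data.frame(topic = k, trait = trait, tranche = tranche,
                       n = sum(!is.na(s)), beta_hat = NA_real_, se = NA_real_,
                       t = NA_real_, p = NA_real_, sr2 = NA_real_,
                       partial_r2 = NA_real_)
          } else {
            fit_topic_prs(theta[, k], s, covars,
                          topic = k, trait = trait, tranche = tranche)
          }
      }
    }
  }
  tab <- do.call(rbind, lapply(rows, function(r) { attr(r, "fit") <- NULL; as.data.frame(r) }))
  n_tested <- sum(!is.na(tab$p))
  tab$p_bonf <- pmin(1, tab$p * n_tested)
  tab$p_bh <- p.adjust(tab$p, method = "BH")
  mats <- lapply(names(profiles), function(trait) {
    sub <- tab[tab$trait == trait, ]
    m <- matrix(NA_real_, length(topics), length(unique(sub$tranche)),
                dimnames = list(paste0("topic", topics), unique(sub$tranche)))
    for (i in seq_len(nrow(sub))) {
      m[paste0("topic", sub$topic[i]), sub$tranche[i]] <- -log10(sub$p[i])
    }
    m
  })
  names(mats) <- names(profiles)
  list(table = tab, neglog10p = mats)
}
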