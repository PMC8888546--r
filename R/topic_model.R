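#' LDA sampler configuration
#'
#' Defaults follow the standard comorbidity-topic-modelling settings: 2000
#' Gibbs iterations with a burn-in of 1000 and thinning of 500, and symmetric
#' Dirichlet priors alpha = 0.1 (document-topic) and beta = 0.01 (topic-term)
#' chosen so topics are well separated. With these defaults the retained
#' samples are the states at iterations 1500 and 2000.
#'
#' @param n_topics number of topics K.
#' @param alpha symmetric document-topic Dirichlet concentration.
#' @param beta symmetric topic-term Dirichlet concentration.
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded before retaining samples.
#' @param thin spacing between retained samples after burn-in.
#' @param seed RNG seed (NULL = leave the RNG state alone).
#' @return an object of class `lda_config`.
#' @export
lda_config <- function(n_topics, alpha = 0.1, beta = 0.01, n_iter = 2000L,
                       burn_in = 1000L, thin = 500L, seed = NULL) {
  stopifnot(n_topics >= 1, alpha > 0, beta > 0, thin >= 1,
            burn_in >= 0, burn_in < n_iter)
  structure(list(n_topics = as.integer(n_topics), alpha = alpha, beta = beta,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed),
            class = "lda_config")
}

corpus_to_ids <- function(corpus) {
  vocab <- corpus$vocabulary
  docs <- corpus$documents
  if (!all(unlist(docs) %in% vocab)) stop("corpus contains tokens absent from vocabulary")
  doc_id <- rep(seq_along(docs), lengths(docs)) - 1L
  word_id <- match(unlist(docs), vocab) - 1L
  list(doc = doc_id, word = word_id, D = length(docs), V = length(vocab))
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' phi (term-topic) and theta (document-topic) are reported as posterior means
#' over the retained samples (iterations `burn_in + thin`, `burn_in + 2*thin`,
#' ...); the final-state estimates are also exposed as `phi_last`/`theta_last`
#' for users who prefer a single-draw estimator. Fixed seed implies identical
#' output.
#'
#' @param corpus a `corpus` (see [build_documents()]); every document must be
#'   non-empty.
#' @param config an [lda_config()].
#' @param track_z if TRUE, per-token topic-assignment frequencies over all
#'   post-burn-in iterations are returned (`z_marginals`), useful for
#'   small-corpus posterior checks.
#' @return object of class `topic_model` with `phi` (K x V), `theta` (D x K),
#'   `phi_last`, `theta_last`, `z_final`, `log_likelihood_trace` (collapsed
#'   joint log-probability per iteration), `config`, `vocabulary`,
#'   `doc_subject_map`.
#' @export
fit_lda <- function(corpus, config, track_z = FALSE) {
  stopifnot(inherits(corpus, "corpus"), inherits(config, "lda_config"))
  if (!length(corpus$documents)) stop("empty corpus")
  if (any(lengths(corpus$documents) == 0L)) {
    stop("empty document encountered; drop empty documents before fitting")
  }
  ids <- corpus_to_ids(corpus)
  K <- config$n_topics
  if (ids$V < K) warning("fewer vocabulary terms than topics (V < K)")
  n_ret <- (config$n_iter - config$burn_in) %/% config$thin
  if (n_ret < 1L) {
    warning("thinning schedule retains no sample; using the final state only")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- lda_gibbs_cpp(ids$doc, ids$word, ids$D, ids$V, K,
                       config$alpha, config$beta, config$n_iter,
                       config$burn_in, config$thin, track_z)
  if (res$n_retained > 0L) {
    phi <- res$phi_sum / res$n_retained
    theta <- res$theta_sum / res$n_retained
  } else {
    phi <- res$phi_last
    theta <- res$theta_last
  }
  dimnames(phi) <- list(paste0("topic", seq_len(K)), corpus$vocabulary)
  dimnames(theta) <- list(corpus$doc_subject_map, paste0("topic", seq_len(K)))
  dimnames(res$phi_last) <- dimnames(phi)
  dimnames(res$theta_last) <- dimnames(theta)
  structure(list(
    phi = phi, theta = theta,
    phi_last = res$phi_last, theta_last = res$theta_last,
    z_final = res$z_final + 1L,
    z_marginals = if (track_z) res$z_marginals else NULL,
    log_likelihood_trace = res$loglik,
    n_retained = res$n_retained,
    config = config, vocabulary = corpus$vocabulary,
    doc_subject_map = corpus$doc_subject_map
  ), class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("topic_model: K = %d topics, V = %d terms, D = %d documents (%d retained samples)\n",
              nrow(x$phi), ncol(x$phi), nrow(x$theta), x$n_retained))
  invisible(x)
}

#' Held-out per-token perplexity by document completion
#'
#' Each held-out document is split into two halves (alternating tokens); theta
#' is estimated from the first half by fold-in Gibbs with phi fixed, and the
#' perplexity of the second half under `sum_k theta_k phi_kw` is reported.
#'
#' @param model a fitted `topic_model`.
#' @param corpus held-out documents (same vocabulary).
#' @param fold_in_iter,fold_in_burn fold-in Gibbs schedule.
#' @return per-token perplexity (exp of mean negative log-likelihood).
#' @export
heldout_perplexity <- function(model, corpus, fold_in_iter = 120L,
                               fold_in_burn = 40L) {
  stopifnot(inherits(model, "topic_model"))
  vocab <- model$vocabulary
  ll <- 0
  n_tok <- 0L
  for (doc in corpus$documents) {
    w <- match(doc, vocab)
    w <- w[!is.na(w)]
    if (length(w) < 2L) next
    idx <- seq_along(w)
    first <- w[idx %% 2L == 1L]
    second <- w[idx %% 2L == 0L]
    if (!length(second)) next
    theta <- lda_fold_in_cpp(first - 1L, model$phi, model$config$alpha,
                             fold_in_iter, fold_in_burn)
    pw <- as.numeric(theta %*% model$phi[, second, drop = FALSE])
    ll <- ll + sum(log(pw))
    n_tok <- n_tok + length(second)
  }
  if (n_tok == 0L) stop("no evaluable held-out tokens")
  exp(-ll / n_tok)
}

topic_coherence <- function(model, corpus, n_top = 10L) {
  # UMass coherence: sum over ordered top-term pairs of
  # log((co-doc frequency + 1) / doc frequency of the conditioning term)
  vocab <- model$vocabulary
  docsets <- lapply(corpus$documents, function(d) unique(match(d, vocab)))
  V <- length(vocab)
  df <- tabulate(unlist(docsets), nbins = V)
  per_topic <- apply(model$phi, 1L, function(p) {
    top <- order(-p, vocab)[seq_len(min(n_top, V))]
    sc <- 0
    for (m in 2:length(top)) {
      for (l in 1:(m - 1)) {
        co <- sum(vapply(docsets, function(s) top[m] %in% s && top[l] %in% s,
                         logical(1)))
        sc <- sc + log((co + 1) / max(df[top[l]], 1L))
      }
    }
    sc
  })
  mean(per_topic)
}

topic_exclusivity <- function(model, n_top = 10L) {
  # mean share of a top term's probability mass owned by its topic
  phi <- model$phi
  colmass <- colSums(phi)
  per_topic <- apply(phi, 1L, function(p) {
    top <- order(-p, colnames(phi))[seq_len(min(n_top, ncol(phi)))]
    mean(p[top] / colmass[top])
  })
  mean(per_topic)
}

#' Select the number of topics
#'
#' Runs candidate models over a grid of K and scores each by (i) held-out
#' per-token perplexity via cross-validated document completion, (ii) mean
#' semantic coherence of top terms (UMass), and (iii) mean term exclusivity.
#' The selected K maximises the mean of the min-max-normalised negated
#' perplexity and exclusivity: a sensitivity/specificity trade-off in which
#' held-out fit rewards topics that explain co-occurring conditions
#' (sensitivity) and exclusivity rewards topics whose top terms are not shared
#' (term specificity). Coherence is monotone in K on presence/absence corpora
#' (it favours the smallest grid value by construction), so it is reported as
#' a diagnostic but kept out of the composite. All per-K metrics are reported
#' so users can re-weight.
#'
#' @param corpus a `corpus`.
#' @param candidate_K integer vector of candidate topic counts (each >= 2).
#' @param config template [lda_config()]; `n_topics` is overridden per
#'   candidate.
#' @param n_folds cross-validation folds for held-out perplexity.
#' @param n_top number of top terms used by coherence/exclusivity.
#' @param seed RNG seed for fold assignment and sampler runs.
#' @return object of class `topic_diagnostics`: data.frame `metrics`
#'   (K, perplexity, coherence, exclusivity, composite) and `selected_K`.
#' @export
select_num_topics <- function(corpus, candidate_K,
                              config = lda_config(2L, n_iter = 400L,
                                                  burn_in = 200L, thin = 20L),
                              n_folds = 2L, n_top = 10L, seed = 1L) {
  stopifnot(length(candidate_K) >= 1L, all(candidate_K >= 2L))
  V <- length(corpus$vocabulary)
  keep <- candidate_K <= V
  if (any(!keep)) {
    warning("skipping candidate K > V: ", paste(candidate_K[!keep], collapse = ", "))
    candidate_K <- candidate_K[keep]
  }
  if (!length(candidate_K)) stop("no usable candidate K")
  D <- length(corpus$documents)
  set.seed(derive_seed(seed, "k-folds"))
  fold <- sample(rep_len(seq_len(n_folds), D))
  metrics <- data.frame(K = sort(unique(candidate_K)), perplexity = NA_real_,
                        coherence = NA_real_, exclusivity = NA_real_)
  for (r in seq_len(nrow(metrics))) {
    K <- metrics$K[r]
    perp <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      cfg <- config
      cfg$n_topics <- as.integer(K)
      cfg$seed <- derive_seed(seed, sprintf("lda-K%d-fold%d", K, f))
      m <- fit_lda(new_corpus(corpus$documents[tr], corpus$vocabulary,
                              corpus$doc_subject_map[tr]), cfg)
      set.seed(derive_seed(seed, sprintf("foldin-K%d-fold%d", K, f)))
      perp[f] <- heldout_perplexity(
        m, new_corpus(corpus$documents[te], corpus$vocabulary,
                      corpus$doc_subject_map[te]))
    }
    cfg <- config
    cfg$n_topics <- as.integer(K)
    cfg$seed <- derive_seed(seed, sprintf("lda-K%d-full", K))
    full <- fit_lda(corpus, cfg)
    metrics$perplexity[r] <- mean(perp)
    metrics$coherence[r] <- topic_coherence(full, corpus, n_top = n_top)
    metrics$exclusivity[r] <- topic_exclusivity(full, n_top = n_top)
  }
  norm01 <- function(x) {
    rng <- range(x)
    if (diff(rng) < .Machine$double.eps) return(rep(0.5, length(x)))
    (x - rng[1]) / diff(rng)
  }
  metrics$composite <- (norm01(-metrics$perplexity) +
                          norm01(metrics$exclusivity)) / 2
  selected <- metrics$K[which.max(metrics$composite)]
  structure(list(metrics = metrics, selected_K = selected,
                 candidate_K = metrics$K),
            class = "topic_diagnostics")
}

#' @export
print.topic_diagnostics <- function(x, ...) {
  cat("topic_diagnostics: selected K =", x$selected_K, "\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Top terms per topic
#'
#' Terms are rank-ordered within topic by phi (descending, ties broken
#' lexicographically) and truncated to `n_terms` (default 16 comorbid
#' conditions per topic). Each term is annotated with whether its probability
#' reaches `beta_mark` (the conventional dashed-line mark at 0.05).
#'
#' @param model a fitted `topic_model`.
#' @param n_terms terms per topic (values above V return all terms).
#' @param beta_mark annotation threshold on phi.
#' @return data.frame with columns topic, rank, term, phi, above_mark.
#' @export
top_terms <- function(model, n_terms = 16L, beta_mark = 0.05) {
  stopifnot(inherits(model, "topic_model"))
  V <- ncol(model$phi)
  n_terms <- min(n_terms, V)
  out <- lapply(seq_len(nrow(model$phi)), function(k) {
    p <- model$phi[k, ]
    ord <- order(-p, colnames(model$phi))[seq_len(n_terms)]
    data.frame(topic = k, rank = seq_len(n_terms),
               term = colnames(model$phi)[ord], phi = unname(p[ord]),
               above_mark = unname(p[ord]) >= beta_mark)
  })
  do.call(rbind, out)
}
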