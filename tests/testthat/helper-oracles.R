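# Independent reference implementations used to validate the package's
# algorithms. Deliberately naive: written for transparency, not speed, and
# sharing no code with the implementations they check.

# 1-D 2-means by naive split-point search: for every threshold between
# consecutive sorted values, compute the within-cluster sum of squares with
# explicit loops and keep the best.
oracle_kmeans_1d <- function(values) {
  obs <- sort(values[!is.na(values)])
  best_wcss <- Inf
  best_cut <- NA_real_
  for (i in seq_len(length(obs) - 1L)) {
    lo <- obs[1:i]
    hi <- obs[(i + 1):length(obs)]
    wcss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (wcss < best_wcss) {
      best_wcss <- wcss
      best_cut <- (obs[i] + obs[i + 1]) / 2
    }
  }
  labels <- ifelse(is.na(values), NA_integer_, as.integer(values > best_cut))
  list(labels = labels, cut_point = best_cut, wcss = best_wcss)
}

# exact z-posterior of collapsed LDA by enumerating all K^N topic assignments
# and weighting by the Dirichlet-multinomial joint probability
oracle_lda_enum <- function(doc, word, D, V, K, alpha, beta) {
  N <- length(doc)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  logw <- apply(grid, 1L, function(z) {
    lp <- 0
    for (d in seq_len(D)) {
      ndk <- tabulate(z[doc == d], nbins = K)
      lp <- lp + lgamma(K * alpha) - lgamma(sum(ndk) + K * alpha) +
        sum(lgamma(ndk + alpha) - lgamma(alpha))
    }
    for (k in seq_len(K)) {
      nkw <- tabulate(word[z == k], nbins = V)
      lp <- lp + lgamma(V * beta) - lgamma(sum(nkw) + V * beta) +
        sum(lgamma(nkw + beta) - lgamma(beta))
    }
    lp
  })
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  marg <- matrix(0, N, K)
  for (i in seq_len(N)) {
    for (k in seq_len(K)) marg[i, k] <- sum(w[grid[, i] == k])
  }
  marg
}

# naive greedy clumping, re-deriving the rule with explicit loops
oracle_clump <- function(stats, geno, window_bp, r2_min) {
  df <- stats[order(stats$P, stats$CHR, stats$BP, stats$SNP), ]
  claimed <- rep(FALSE, nrow(df))
  retained <- character(0)
  repeat {
    avail <- which(!claimed)
    if (!length(avail)) break
    i <- avail[1]
    retained <- c(retained, df$SNP[i])
    claimed[i] <- TRUE
    for (j in which(!claimed)) {
      if (df$CHR[j] != df$CHR[i]) next
      if (abs(df$BP[j] - df$BP[i]) > window_bp) next
      x <- geno$dosages[, match(df$SNP[i], geno$variants$id)]
      y <- geno$dosages[, match(df$SNP[j], geno$variants$id)]
      r <- suppressWarnings(cor(x, y, use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 >= r2_min) claimed[j] <- TRUE
    }
  }
  retained
}

# drop-one refit oracle for semi-partial R^2, via lm() formulas from scratch
oracle_sr2 <- function(y, predictors) {
  df <- data.frame(y = y, predictors, check.names = FALSE)
  r2 <- function(vars) {
    if (!length(vars)) return(0)
    f <- as.formula(paste("y ~", paste(sprintf("`%s`", vars), collapse = "+")))
    summary(lm(f, data = df))$r.squared
  }
  full <- r2(names(predictors))
  vapply(names(predictors), function(nm) {
    full - r2(setdiff(names(predictors), nm))
  }, numeric(1))
}

# small random clumping instance: blocks of correlated SNPs on two chromosomes
random_clump_instance <- function(seed, n_snps = 60L, n_sub = 120L) {
  set.seed(seed)
  cfg <- sim_config(n_subjects = n_sub, n_snps = n_snps,
                    ld_block_size = sample(3:8, 1), ld_rho = runif(1, 0.3, 0.95),
                    n_causal = max(1L, n_snps %/% 10L), seed = seed)
  g <- simulate_genotypes(cfg)
  # compress positions so windows overlap irregularly
  g$stats$BP <- sample.int(600000L, n_snps)
  g$geno$variants$pos <- g$stats$BP
  g
}
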