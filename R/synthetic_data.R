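#' Simulation configuration
#'
#' Defines the generating conditions for the synthetic study: a
#' Dirichlet-multinomial topic structure for pseudo-EMR documents, biallelic
#' SNP genotypes in exchangeable-correlation LD blocks, an external GWAS
#' simulated on an independent discovery cohort of the same size, and a linear
#' effect of standardized true polygenic burden on one topic's latent loading
#' (applied on the log/softmax scale).
#'
#' Defaults: 1000 subjects; 5 true topics over a 300-term vocabulary with ~30
#' tokens per document, so that roughly a tenth of candidate conditions are
#' present per subject - the sparse presence regime of clinical phenotype
#' tables, which keeps topics identifiable after documents are reduced to
#' presence sets; document-topic concentration 0.5 (subjects load on a few
#' comorbidity clusters, not a single one) and topic-term concentration 0.05
#' (concentrated, largely distinct topics); 2000 SNPs in blocks of 10 with
#' within-block latent correlation 0.8 and minor-allele frequencies in
#' [0.05, 0.5]; 50 causal SNPs with effects of SD 0.2 on a unit-noise
#' liability; planted topic effect 0.3 SD per SD of burden on topic 1.
#'
#' @param n_subjects target-cohort size (the discovery GWAS cohort has the
#'   same size).
#' @param n_topics_true,vocab_size,tokens_per_doc_mean corpus dimensions.
#' @param alpha_true,beta_true Dirichlet concentrations of the true
#'   document-topic and topic-term distributions.
#' @param n_snps,n_causal,ld_block_size,ld_rho,maf_range,effect_sd genotype
#'   and GWAS generating parameters; `ld_rho` in `[0, 1)`, MAF bounds in
#'   `(0, 0.5]`.
#' @param prs_topic_effect planted linear effect of standardized burden on the
#'   target topic loading, in loading-SD per burden-SD (see
#'   [link_prs_to_topic()]).
#' @param target_topic index of the topic carrying the planted effect.
#' @param seed global RNG seed; stage seeds are derived from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 1000L, n_topics_true = 5L,
                       vocab_size = 300L, tokens_per_doc_mean = 30L,
                       alpha_true = 0.5, beta_true = 0.05,
                       n_snps = 2000L, n_causal = 50L, ld_block_size = 10L,
                       ld_rho = 0.8, maf_range = c(0.05, 0.5),
                       effect_sd = 0.2, prs_topic_effect = 0.3,
                       target_topic = 1L, seed = 1L) {
  counts <- c(n_subjects = n_subjects, n_topics_true = n_topics_true,
              vocab_size = vocab_size, tokens_per_doc_mean = tokens_per_doc_mean,
              n_snps = n_snps, ld_block_size = ld_block_size)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (n_causal < 0 || n_causal > n_snps) stop("need 0 <= n_causal <= n_snps")
  if (vocab_size < n_topics_true) stop("vocab_size must be >= n_topics_true")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range bounds must lie in (0, 0.5] and be ordered")
  }
  if (target_topic < 1 || target_topic > n_topics_true) {
    stop("target_topic out of range")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_topics_true = as.integer(n_topics_true),
                 vocab_size = as.integer(vocab_size),
                 tokens_per_doc_mean = as.integer(tokens_per_doc_mean),
                 alpha_true = alpha_true, beta_true = beta_true,
                 n_snps = as.integer(n_snps), n_causal = as.integer(n_causal),
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
                 maf_range = maf_range, effect_sd = effect_sd,
                 prs_topic_effect = prs_topic_effect,
                 target_topic = as.integer(target_topic),
                 seed = as.integer(seed)),
            class = "sim_config")
}

subject_ids <- function(n) sprintf("S%04d", seq_len(n))

term_names <- function(v) sprintf("term%03d", seq_len(v))

# draw documents given phi (K x V) and theta (D x K); returns token lists,
# per-token topic assignments and the empirical per-document topic fractions
generate_documents <- function(phi, theta, mean_len) {
  D <- nrow(theta)
  K <- nrow(phi)
  vocab <- term_names(ncol(phi))
  len <- pmax(1L, rpois(D, mean_len))
  docs <- vector("list", D)
  zs <- vector("list", D)
  theta_emp <- matrix(0, D, K)
  for (d in seq_len(D)) {
    z <- sample.int(K, len[d], replace = TRUE, prob = theta[d, ])
    w <- integer(len[d])
    for (k in unique(z)) {
      sel <- z == k
      w[sel] <- sample.int(ncol(phi), sum(sel), replace = TRUE, prob = phi[k, ])
    }
    docs[[d]] <- vocab[w]
    zs[[d]] <- z
    theta_emp[d, ] <- tabulate(z, nbins = K) / len[d]
  }
  list(documents = docs, z = zs, theta_emp = theta_emp, lengths = len)
}

#' Simulate a pseudo-EMR corpus with known topic structure
#'
#' Documents follow the LDA generative process: theta_d ~
#' Dirichlet(alpha_true), per-token topic z ~ Categorical(theta_d), token w ~
#' Categorical(phi_z), with phi rows drawn from Dirichlet(beta_true). Also
#' emits a subject x term binary feature table (presence = term occurs in the
#' document) so the pseudo-EMR stage can be exercised end to end.
#'
#' @param cfg a [sim_config()].
#' @param theta_true optional D x K matrix overriding the drawn document-topic
#'   mixtures (used by [link_prs_to_topic()]).
#' @param phi_true optional K x V matrix overriding the drawn topic-term
#'   distributions.
#' @param seed_label stage label mixed into the derived seed.
#' @return list with `corpus`, `feature_table` and `truth` (phi_true,
#'   theta_true, theta_emp, z, target_topic).
#' @export
simulate_corpus <- function(cfg, theta_true = NULL, phi_true = NULL,
                            seed_label = "corpus") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, seed_label))
  K <- cfg$n_topics_true
  V <- cfg$vocab_size
  D <- cfg$n_subjects
  if (is.null(phi_true)) phi_true <- rdirichlet(K, rep(cfg$beta_true, V))
  if (is.null(theta_true)) theta_true <- rdirichlet(D, rep(cfg$alpha_true, K))
  stopifnot(nrow(theta_true) == D, ncol(theta_true) == K, ncol(phi_true) == V)
  gen <- generate_documents(phi_true, theta_true, cfg$tokens_per_doc_mean)
  ids <- subject_ids(D)
  corp <- new_corpus(gen$documents, term_names(V), ids)
  present <- t(vapply(gen$documents,
                      function(d) as.integer(term_names(V) %in% d),
                      integer(V)))
  colnames(present) <- term_names(V)
  ft <- feature_table(as.data.frame(present), ids,
                      kinds = setNames(rep("binary", V), term_names(V)))
  ft$binarized <- TRUE
  truth <- list(phi_true = phi_true, theta_true = theta_true,
                theta_emp = gen$theta_emp, z = gen$z,
                target_topic = cfg$target_topic)
  list(corpus = corp, feature_table = ft, truth = truth)
}

# exchangeable-correlation latent-Gaussian haplotypes for one cohort
sim_dosages <- function(n, maf, block, rho) {
  n_snps <- length(maf)
  thresh <- qnorm(maf)
  dos <- matrix(0L, n, n_snps)
  for (b in unique(block)) {
    js <- which(block == b)
    for (gamete in 1:2) {
      shared <- rnorm(n)
      z <- sqrt(rho) * shared +
        sqrt(1 - rho) * matrix(rnorm(n * length(js)), n)
      dos[, js] <- dos[, js] + (z < rep(thresh[js], each = n))
    }
  }
  dos
}

# marginal per-SNP OLS of liability on dosage
marginal_gwas <- function(X, y) {
  n <- nrow(X)
  xm <- colMeans(X)
  ym <- mean(y)
  ssx <- colSums(X^2) - n * xm^2
  sxy <- as.numeric(crossprod(X, y)) - n * xm * ym
  beta <- sxy / ssx
  rss <- sum((y - ym)^2) - beta * sxy
  se <- sqrt(pmax(rss, 0) / (n - 2) / ssx)
  t <- beta / se
  p <- 2 * pt(-abs(t), df = n - 2)
  p <- pmax(p, .Machine$double.xmin)
  list(beta = beta, se = se, p = p, freq = xm / 2)
}

#' Simulate genotypes, GWAS summary statistics and a reference panel
#'
#' Target-cohort dosages are drawn from a latent Gaussian with
#' block-exchangeable correlation `ld_rho`, thresholded at the minor-allele
#' frequency per haplotype (dosages in 0/1/2, ALT = effect allele). Causal
#' effects `~ Normal(0, effect_sd^2)` act on `n_causal` SNPs; summary
#' statistics come from per-SNP marginal regression of a unit-noise liability
#' on dosage in an independently simulated discovery cohort of the same size,
#' so PRS transfer to the target cohort is honest. The reference panel reports
#' the true generating allele frequencies. SNP alleles are drawn uniformly
#' over A/C/G/T pairs, so a realistic fraction is strand-ambiguous and
#' removable by QC. Blocks are laid out 5 kb apart within a block and 10 Mb
#' between blocks, cycling over 22 chromosomes.
#'
#' @param cfg a [sim_config()].
#' @param n_null_traits additional GWAS traits generated from their own causal
#'   SNP sets (liabilities on the same discovery cohort) with no planted link
#'   to any topic; returned as `null_stats`.
#' @return list with `geno` (target [genotype_matrix()]), `stats` (summary
#'   statistics of the burden-defining trait), `null_stats` (named list),
#'   `ref` (reference panel), and `truth` (causal_effects, causal_idx,
#'   true_burden, maf).
#' @export
simulate_genotypes <- function(cfg, n_null_traits = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "genotypes"))
  m <- cfg$n_snps
  n <- cfg$n_subjects
  maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  block <- (seq_len(m) - 1L) %/% cfg$ld_block_size
  chrom <- (block %% 22L) + 1L
  within <- ave(seq_len(m), block, FUN = seq_along)
  pos <- (block %/% 22L) * 10000000L + within * 5000L
  pairs <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  pick <- sample.int(nrow(pairs), m, replace = TRUE)
  variants <- data.frame(id = sprintf("rs%06d", seq_len(m)), chrom = chrom,
                         pos = pos, ref = pairs$ref[pick], alt = pairs$alt[pick],
                         stringsAsFactors = FALSE)

  X_target <- sim_dosages(n, maf, block, cfg$ld_rho)
  dimnames(X_target) <- list(subject_ids(n), variants$id)
  X_disc <- sim_dosages(n, maf, block, cfg$ld_rho)

  effects <- numeric(m)
  causal_idx <- if (cfg$n_causal > 0) sort(sample.int(m, cfg$n_causal)) else integer(0)
  effects[causal_idx] <- rnorm(cfg$n_causal, 0, cfg$effect_sd)
  make_stats <- function(eff) {
    y <- as.numeric(X_disc %*% eff) + rnorm(n)
    g <- marginal_gwas(X_disc, y)
    data.frame(SNP = variants$id, CHR = variants$chrom, BP = variants$pos,
               A1 = variants$alt, A2 = variants$ref, BETA = g$beta,
               FREQ = g$freq, P = g$p, stringsAsFactors = FALSE)
  }
  stats <- make_stats(effects)
  null_stats <- list()
  if (n_null_traits > 0) {
    for (j in seq_len(n_null_traits)) {
      eff_null <- numeric(m)
      idx <- if (cfg$n_causal > 0) sample.int(m, cfg$n_causal) else integer(0)
      eff_null[idx] <- rnorm(length(idx), 0, cfg$effect_sd)
      null_stats[[paste0("null_trait", j)]] <- make_stats(eff_null)
    }
  }
  ref <- data.frame(SNP = variants$id, CHR = variants$chrom, BP = variants$pos,
                    A1 = variants$alt, A2 = variants$ref, FREQ = maf,
                    stringsAsFactors = FALSE)
  truth <- list(causal_effects = effects, causal_idx = causal_idx,
                true_burden = as.numeric(X_target %*% effects), maf = maf)
  list(geno = genotype_matrix(X_target, variants), stats = stats,
       null_stats = null_stats, ref = ref, truth = truth)
}

#' Plant a polygenic effect on one topic and regenerate documents
#'
#' Shifts the target topic's latent loading on the log scale (renormalised by
#' softmax) in proportion to the standardized true burden, then regenerates
#' documents from the shifted mixtures, so the downstream association stage
#' has a known positive signal to recover. `prs_topic_effect` is expressed in
#' interpretable units - loading standard deviations per burden standard
#' deviation - and the log-scale coefficient is calibrated to deliver that
#' linear effect via the softmax derivative `theta * (1 - theta)` averaged
#' over the base mixtures. With `prs_topic_effect = 0` the output is
#' distributed exactly as [simulate_corpus()] output.
#'
#' @param theta_true base document-topic mixtures (D x K).
#' @param true_burden per-subject true polygenic burden (length D).
#' @param cfg a [sim_config()].
#' @param phi_true topic-term distributions used to regenerate documents.
#' @return as [simulate_corpus()]; `truth$theta_true` is the shifted mixture
#'   and `truth$true_burden` is carried along.
#' @export
link_prs_to_topic <- function(theta_true, true_burden, cfg, phi_true) {
  stopifnot(inherits(cfg, "sim_config"),
            nrow(theta_true) == length(true_burden),
            ncol(theta_true) == cfg$n_topics_true)
  if (cfg$target_topic < 1 || cfg$target_topic > ncol(theta_true)) {
    stop("target_topic out of range")
  }
  b <- true_burden
  if (sd(b) > 0) b <- (b - mean(b)) / sd(b)
  tt <- cfg$target_topic
  # prs_topic_effect is in loading-SD per burden-SD units; the shift is
  # applied on the log scale, where d theta / d shift = theta * (1 - theta),
  # so the log-scale coefficient is calibrated against the base mixtures
  s_t <- sd(theta_true[, tt])
  m_t <- mean(theta_true[, tt] * (1 - theta_true[, tt]))
  shift <- if (m_t > 0 && s_t > 0) cfg$prs_topic_effect * s_t / m_t else 0
  a <- log(pmax(theta_true, 1e-300))
  a[, tt] <- a[, tt] + shift * b
  theta_shift <- softmax_rows(a)
  out <- simulate_corpus(cfg, theta_true = theta_shift, phi_true = phi_true,
                         seed_label = "corpus-linked")
  out$truth$true_burden <- true_burden
  out
}

#' Write the simulation ground truth as a JSON sidecar
#'
#' @param truth a truth list from [simulate_corpus()], [simulate_genotypes()]
#'   or [link_prs_to_topic()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  truth$z <- NULL # token-level assignments are bulky and reconstructible
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
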