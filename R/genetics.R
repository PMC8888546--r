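#' Construct a genotype matrix
#'
#' @param dosages numeric matrix, subjects x variants, entries in `[0, 2]` or
#'   NA; rownames are subject ids, colnames are variant ids.
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, one row per column of `dosages`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants) {
  dosages <- as.matrix(dosages)
  stopifnot(ncol(dosages) == nrow(variants),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)))
  if (is.null(colnames(dosages))) colnames(dosages) <- variants$id
  if (is.null(rownames(dosages))) rownames(dosages) <- paste0("S", seq_len(nrow(dosages)))
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  if (any(variants$pos <= 0)) stop("positions must be positive")
  key <- with(variants, paste(chrom, pos, ref, alt))
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, ref, alt) variants")
  variants <- as.data.frame(variants)
  variants$chrom <- as.character(variants$chrom)
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d variants (%.1f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' PRS configuration
#'
#' Default p-value tranches are the seven standard ceilings S2-S8 (1e-2 down
#' to genome-wide significance 5e-8); each tranche includes every SNP whose
#' GWAS p-value is at most the ceiling, so tranche SNP sets are nested.
#' Clumping defaults: 250 kb window, r^2 threshold 0.5. QC defaults: call rate
#' 0.9 for SNPs and samples, HWE p > 1e-6, reference-panel allele-frequency
#' difference at most 0.2, ambiguous (A/T, C/G) SNPs dropped.
#'
#' @param tranches named numeric vector of strictly decreasing maximum
#'   p-values.
#' @param clump_window_kb clumping window in kilobases.
#' @param clump_r2 r-squared at or above which a neighbour is clumped.
#' @param snp_call_rate,sample_call_rate minimum call rates.
#' @param hwe_p SNPs with Hardy-Weinberg p-value <= this are dropped.
#' @param ref_freq_diff maximum |sample - reference| allele-frequency difference.
#' @param drop_ambiguous drop A/T and C/G SNPs.
#' @return object of class `prs_config`.
#' @export
prs_config <- function(tranches = c(S2 = 1e-2, S3 = 1e-3, S4 = 1e-4, S5 = 1e-5,
                                    S6 = 1e-6, S7 = 1e-7, S8 = 5e-8),
                       clump_window_kb = 250, clump_r2 = 0.5,
                       snp_call_rate = 0.9, sample_call_rate = 0.9,
                       hwe_p = 1e-6, ref_freq_diff = 0.2,
                       drop_ambiguous = TRUE) {
  stopifnot(all(diff(tranches) < 0), clump_r2 > 0, clump_r2 < 1,
            clump_window_kb > 0)
  if (is.null(names(tranches))) names(tranches) <- paste0("T", seq_along(tranches))
  structure(list(tranches = tranches, clump_window_kb = clump_window_kb,
                 clump_r2 = clump_r2, snp_call_rate = snp_call_rate,
                 sample_call_rate = sample_call_rate, hwe_p = hwe_p,
                 ref_freq_diff = ref_freq_diff,
                 drop_ambiguous = drop_ambiguous),
            class = "prs_config")
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' expectations under allele frequencies estimated from the sample; the
#' conventional array-QC choice. The exact test (summing the conditional
#' probability of heterozygote counts as or less probable than the observed
#' one) is available via `method = "exact"`. Monomorphic input returns p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return p-value.
#' @export
hardy_weinberg_p <- function(n_AA, n_Aa, n_aa, method = c("chisq", "exact")) {
  method <- match.arg(method)
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) stop("counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("total count must be positive")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  if (method == "chisq") {
    expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((counts - expected)^2 / expected)
    return(pchisq(stat, df = 1, lower.tail = FALSE))
  }
  # exact: condition on allele counts; enumerate heterozygote counts of the
  # same parity, sum probabilities <= that of the observed configuration
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  het <- seq(nA %% 2, min(nA, na), by = 2)
  logp <- lgamma(n + 1) - lgamma((nA - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((na - het) / 2 + 1) + het * log(2) +
    lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, het)]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

is_ambiguous_pair <- function(a1, a2) {
  paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")
}

complement_allele <- function(a) chartr("ACGT", "TGCA", a)

#' QC-filter genotypes and harmonize GWAS summary statistics
#'
#' Applies array-style QC in order: sample call rate, SNP call rate,
#' Hardy-Weinberg equilibrium (chi-square on hard-called genotypes), removal
#' of strand-ambiguous (A/T, C/G) SNPs, removal of SNPs absent from the
#' reference panel or differing from its allele frequency by more than the
#' configured bound. Summary statistics are then harmonized so the effect
#' applies to the genotype ALT (dosage-counted) allele: matching allele order
#' keeps beta, swapped order negates beta and reflects the frequency, and a
#' non-ambiguous strand flip is resolved by complementing the alleles;
#' unresolvable SNPs are dropped with a reason.
#'
#' @param geno a [genotype_matrix()].
#' @param stats summary-statistics data.frame (`SNP CHR BP A1 A2 BETA FREQ P`
#'   columns, lower-case accepted via [read_sumstats()]).
#' @param ref reference panel data.frame (`SNP A1 A2 FREQ`), frequencies of A1.
#' @param config a [prs_config()].
#' @return list with filtered `geno`, harmonized `stats` (effects on the ALT
#'   allele of surviving genotype SNPs), and `report` (data.frame item, type,
#'   reason for every removed sample/SNP).
#' @export
qc_filter <- function(geno, stats, ref, config = prs_config()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  report <- data.frame(item = character(), type = character(), reason = character())
  note <- function(items, type, reason) {
    if (length(items)) {
      report <<- rbind(report, data.frame(item = items, type = type, reason = reason))
    }
  }
  dos <- geno$dosages
  var <- geno$variants

  scr <- rowMeans(!is.na(dos))
  drop_s <- rownames(dos)[scr < config$sample_call_rate]
  note(drop_s, "sample", "call rate below threshold")
  dos <- dos[scr >= config$sample_call_rate, , drop = FALSE]

  vcr <- colMeans(!is.na(dos))
  bad <- vcr < config$snp_call_rate
  note(var$id[bad], "snp", "call rate below threshold")

  hard <- round(dos)
  hwe <- vapply(seq_len(ncol(hard)), function(j) {
    g <- hard[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hardy_weinberg_p(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  bad_hwe <- !bad & hwe <= config$hwe_p
  note(var$id[bad_hwe], "snp", "Hardy-Weinberg disequilibrium")
  bad <- bad | bad_hwe

  if (config$drop_ambiguous) {
    amb <- !bad & is_ambiguous_pair(var$ref, var$alt)
    note(var$id[amb], "snp", "ambiguous alleles")
    bad <- bad | amb
  }

  ridx <- match(var$id, ref$SNP)
  absent <- !bad & is.na(ridx)
  note(var$id[absent], "snp", "not in reference panel")
  bad <- bad | absent

  alt_freq <- colMeans(dos, na.rm = TRUE) / 2
  ref_alt_freq <- rep(NA_real_, nrow(var))
  ok <- !is.na(ridx)
  if (any(ok)) {
    rA1 <- ref$A1[ridx[ok]]
    rA2 <- ref$A2[ridx[ok]]
    f <- ref$FREQ[ridx[ok]]
    raf <- ifelse(rA1 == var$alt[ok] & rA2 == var$ref[ok], f,
           ifelse(rA1 == var$ref[ok] & rA2 == var$alt[ok], 1 - f,
           ifelse(complement_allele(rA1) == var$alt[ok] &
                  complement_allele(rA2) == var$ref[ok], f,
           ifelse(complement_allele(rA1) == var$ref[ok] &
                  complement_allele(rA2) == var$alt[ok], 1 - f, NA_real_))))
    ref_alt_freq[ok] <- raf
  }
  mismatch <- !bad & !is.na(ridx) &
    (is.na(ref_alt_freq) | abs(alt_freq - ref_alt_freq) > config$ref_freq_diff)
  note(var$id[mismatch], "snp", "allele frequency differs from reference panel")
  bad <- bad | mismatch

  if (all(bad)) stop("EmptyPanelError: no SNPs survived QC")
  geno_out <- genotype_matrix(dos[, !bad, drop = FALSE], var[!bad, , drop = FALSE])

  # harmonize summary statistics to the surviving genotype SNPs
  sidx <- match(geno_out$variants$id, stats$SNP)
  keep_rows <- integer(0)
  beta_out <- numeric(0)
  freq_out <- numeric(0)
  for (j in which(!is.na(sidx))) {
    s <- stats[sidx[j], ]
    alt <- geno_out$variants$alt[j]
    refa <- geno_out$variants$ref[j]
    resolved <- FALSE
    a1 <- s$A1; a2 <- s$A2
    for (flip in c(FALSE, TRUE)) {
      if (flip) {
        if (is_ambiguous_pair(a1, a2)) break
        a1 <- complement_allele(a1); a2 <- complement_allele(a2)
      }
      if (a1 == alt && a2 == refa) {
        beta <- s$BETA; freq <- s$FREQ; resolved <- TRUE; break
      }
      if (a1 == refa && a2 == alt) {
        beta <- -s$BETA; freq <- 1 - s$FREQ; resolved <- TRUE; break
      }
    }
    if (resolved) {
      keep_rows <- c(keep_rows, j)
      beta_out <- c(beta_out, beta)
      freq_out <- c(freq_out, freq)
    } else {
      note(s$SNP, "sumstat", "unresolvable allele coding")
    }
  }
  v <- geno_out$variants[keep_rows, , drop = FALSE]
  stats_out <- data.frame(SNP = v$id, CHR = v$chrom, BP = v$pos,
                          A1 = v$alt, A2 = v$ref, BETA = beta_out,
                          FREQ = freq_out,
                          P = stats$P[sidx[keep_rows]])
  list(geno = geno_out, stats = stats_out, report = report)
}

#' Greedy LD clumping
#'
#' PLINK-style clumping: repeatedly take the unclaimed SNP with the smallest
#' GWAS p-value as an index SNP and claim every unclaimed SNP on the same
#' chromosome within the window whose dosage r-squared with the index reaches
#' the threshold. Ties on p are broken by (chrom, pos, id), making the result
#' independent of input row order.
#'
#' @param stats harmonized summary statistics (must be present in `geno`).
#' @param geno a [genotype_matrix()] supplying dosages for r-squared
#'   (pairwise-complete Pearson correlation, squared).
#' @param config a [prs_config()] (window and r-squared threshold).
#' @return character vector of retained (index) SNP ids, in selection order.
#' @export
ld_clump <- function(stats, geno, config = prs_config()) {
  idx <- match(stats$SNP, geno$variants$id)
  if (anyNA(idx)) stop("summary-stat SNPs missing from genotypes: ",
                       paste(head(stats$SNP[is.na(idx)], 5), collapse = ", "))
  ord <- order(stats$P, stats$CHR, stats$BP, stats$SNP)
  snp <- stats$SNP[ord]
  chr <- as.character(stats$CHR[ord])
  bp <- stats$BP[ord]
  gcol <- idx[ord]
  window <- config$clump_window_kb * 1000
  claimed <- rep(FALSE, length(snp))
  retained <- character(0)
  for (i in seq_along(snp)) {
    if (claimed[i]) next
    claimed[i] <- TRUE
    retained <- c(retained, snp[i])
    near <- which(!claimed & chr == chr[i] & abs(bp - bp[i]) <= window)
    if (!length(near)) next
    x <- geno$dosages[, gcol[i]]
    r2 <- vapply(near, function(j) {
      r <- suppressWarnings(cor(x, geno$dosages[, gcol[j]],
                                use = "pairwise.complete.obs"))
      if (is.na(r)) 0 else r^2
    }, numeric(1))
    claimed[near[r2 >= config$clump_r2]] <- TRUE
  }
  retained
}

#' Score p-value tranche polygenic risk scores
#'
#' For tranche t, subject i: `S_i(t) = sum_j beta_j * d_ij` over retained SNPs
#' with GWAS p at most the tranche ceiling. Missing dosages are mean-imputed
#' (twice the sample effect-allele frequency). Scores are standardized within
#' the cohort (per-SD units); a tranche with zero SNPs or zero variance scores
#' 0 for all subjects and is flagged.
#'
#' @param geno a QC-filtered [genotype_matrix()].
#' @param stats harmonized summary statistics ([qc_filter()] output).
#' @param retained SNP ids surviving [ld_clump()]; NULL uses all of `stats`.
#' @param config a [prs_config()].
#' @param trait trait label.
#' @return object of class `prs_profile`: `scores` (standardized, subjects x
#'   tranches), `raw_scores`, `n_snps`, `snps` (per-tranche id list),
#'   `degenerate` (flagged tranches), `trait`.
#' @export
score_prs <- function(geno, stats, retained = NULL, config = prs_config(),
                      trait = "trait") {
  if (is.null(retained)) retained <- stats$SNP
  stats <- stats[stats$SNP %in% retained, , drop = FALSE]
  n_sub <- nrow(geno$dosages)
  tr <- config$tranches
  raw <- matrix(0, n_sub, length(tr),
                dimnames = list(rownames(geno$dosages), names(tr)))
  std <- raw
  n_snps <- setNames(integer(length(tr)), names(tr))
  snps <- setNames(vector("list", length(tr)), names(tr))
  degenerate <- character(0)
  dos <- geno$dosages[, match(stats$SNP, geno$variants$id), drop = FALSE]
  # mean imputation = 2 * effect-allele frequency in the scored sample
  if (anyNA(dos) && nrow(stats)) {
    cm <- colMeans(dos, na.rm = TRUE)
    nas <- which(is.na(dos), arr.ind = TRUE)
    dos[nas] <- cm[nas[, 2]]
  }
  for (t in seq_along(tr)) {
    sel <- which(stats$P <= tr[t])
    n_snps[t] <- length(sel)
    snps[[t]] <- stats$SNP[sel]
    if (!length(sel)) {
      degenerate <- c(degenerate, names(tr)[t])
      next
    }
    s <- as.numeric(dos[, sel, drop = FALSE] %*% stats$BETA[sel])
    raw[, t] <- s
    sdv <- sd(s)
    if (is.na(sdv) || sdv == 0) {
      degenerate <- c(degenerate, names(tr)[t])
    } else {
      std[, t] <- (s - mean(s)) / sdv
    }
  }
  structure(list(scores = std, raw_scores = raw, n_snps = n_snps, snps = snps,
                 degenerate = degenerate, trait = trait, retained = retained),
            class = "prs_profile")
}

#' @export
print.prs_profile <- function(x, ...) {
  cat(sprintf("prs_profile '%s': %d subjects; SNPs per tranche: %s\n",
              x$trait, nrow(x$scores),
              paste(sprintf("%s=%d", names(x$n_snps), x$n_snps), collapse = " ")))
  invisible(x)
}

#' Genotype principal components
#'
#' Dosages are mean-imputed, centred, and scaled by `sqrt(2 p (1 - p))` with p
#' the sample allele frequency (monomorphic SNPs dropped); the leading left
#' singular vectors of the standardized matrix are returned as orthonormal
#' per-subject scores. Sign convention: each component's largest-magnitude SNP
#' loading is positive.
#'
#' @param geno a [genotype_matrix()].
#' @param n_components number of components (default 5).
#' @return subjects x components matrix of orthonormal scores, with attribute
#'   `sdev` (component standard deviations).
#' @export
genotype_pca <- function(geno, n_components = 5L) {
  X <- geno$dosages
  if (nrow(X) < n_components) stop("fewer subjects than components")
  if (anyNA(X)) {
    cm <- colMeans(X, na.rm = TRUE)
    nas <- which(is.na(X), arr.ind = TRUE)
    X[nas] <- cm[nas[, 2]]
  }
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  if (sum(keep) < n_components) stop("fewer polymorphic SNPs than components")
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  X <- sweep(X, 2L, 2 * p)
  X <- sweep(X, 2L, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(X, nu = n_components, nv = n_components)
  if (sv$d[1] < 1e-12) stop("degenerate genotype matrix: no variance across subjects")
  U <- sv$u
  for (k in seq_len(n_components)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) {
      U[, k] <- -U[, k]
      sv$v[, k] <- -sv$v[, k]
    }
  }
  dimnames(U) <- list(rownames(geno$dosages), paste0("PC", seq_len(n_components)))
  attr(U, "sdev") <- sv$d[seq_len(n_components)] / sqrt(max(1, nrow(X) - 1))
  U
}
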