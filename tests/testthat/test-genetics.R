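# small handmade genotype fixtures -------------------------------------------

make_geno <- function(dosages, chrom = NULL, pos = NULL, ref = NULL, alt = NULL) {
  m <- ncol(dosages)
  variants <- data.frame(
    id = sprintf("snp%02d", seq_len(m)),
    chrom = chrom %||% rep(1L, m),
    pos = pos %||% (seq_len(m) * 1000L),
    ref = ref %||% rep("A", m),
    alt = alt %||% rep("G", m))
  colnames(dosages) <- variants$id
  rownames(dosages) <- paste0("s", seq_len(nrow(dosages)))
  genotype_matrix(dosages, variants)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

stats_for <- function(geno, beta = NULL, p = NULL, a1 = NULL, a2 = NULL,
                      freq = NULL) {
  v <- geno$variants
  data.frame(SNP = v$id, CHR = v$chrom, BP = v$pos,
             A1 = a1 %||% v$alt, A2 = a2 %||% v$ref,
             BETA = beta %||% rep(0.1, nrow(v)),
             FREQ = freq %||% (colMeans(geno$dosages, na.rm = TRUE) / 2),
             P = p %||% rep(1e-3, nrow(v)), stringsAsFactors = FALSE)
}

ref_for <- function(geno, freq = NULL) {
  v <- geno$variants
  data.frame(SNP = v$id, CHR = v$chrom, BP = v$pos, A1 = v$alt, A2 = v$ref,
             FREQ = freq %||% (colMeans(geno$dosages, na.rm = TRUE) / 2),
             stringsAsFactors = FALSE)
}

# Hardy-Weinberg --------------------------------------------------------------

test_that("Hardy-Weinberg chi-square matches hand computations", {
  expect_equal(hardy_weinberg_p(25, 50, 25), 1)
  expect_equal(hardy_weinberg_p(0, 0, 100), 1) # monomorphic
  # (20,40,40): p(A)=0.4, expected (16,48,36), chi2 = 1 + 4/3 + 4/9
  p <- hardy_weinberg_p(20, 40, 40)
  expect_equal(p, pchisq(25 / 9, df = 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(p, 0.0956, tolerance = 1e-3)
  expect_error(hardy_weinberg_p(-1, 2, 3), "non-negative")
  # extreme heterozygote deficit
  expect_lt(hardy_weinberg_p(50, 0, 50), 1e-6)
})

test_that("chi-square and exact Hardy-Weinberg tests agree where they should", {
  # exact test: symmetric enumeration check on a tiny case
  expect_equal(hardy_weinberg_p(1, 0, 1, method = "exact"), 1 / 3,
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    n <- 200
    pa <- runif(1, 0.2, 0.8)
    g <- rbinom(n, 2, pa)
    cnt <- tabulate(g + 1, 3)
    pc <- hardy_weinberg_p(cnt[3], cnt[2], cnt[1])
    pe <- hardy_weinberg_p(cnt[3], cnt[2], cnt[1], method = "exact")
    expect_lt(abs(pc - pe), 0.25) # asymptotic vs exact divergence at n=200
    expect_equal(pc <= 1e-6, pe <= 1e-6) # same QC decision
  }
})

# QC and harmonization --------------------------------------------------------

test_that("QC drops ambiguous SNPs, bad call rates, HWE failures and freq mismatches", {
  set.seed(9)
  n <- 100
  m <- 20
  dos <- matrix(rbinom(n * m, 2, 0.5), n, m)
  dos[, 3] <- rep(c(0, 2), each = n / 2)            # (50,0,50): HWE failure
  dos[1:60, 4] <- NA                                 # SNP call rate 0.4
  ref_al <- rep("A", m); alt_al <- rep("G", m)
  alt_al[5] <- "T"                                   # A/T: strand-ambiguous
  geno <- make_geno(dos, ref = ref_al, alt = alt_al)
  ref <- ref_for(geno)
  ref$FREQ[6] <- ref$FREQ[6] - 0.5                   # freq mismatch > 0.2
  ref <- ref[ref$SNP != "snp02", ]                   # snp02 absent from panel
  stats <- stats_for(geno)
  out <- qc_filter(geno, stats, ref, prs_config())
  expect_setequal(out$geno$variants$id,
                  setdiff(geno$variants$id,
                          c("snp02", "snp03", "snp04", "snp05", "snp06")))
  reasons <- setNames(out$report$reason, out$report$item)
  expect_match(reasons[["snp05"]], "ambiguous")
  expect_match(reasons[["snp03"]], "Hardy-Weinberg")
  expect_match(reasons[["snp04"]], "call rate")
  expect_match(reasons[["snp02"]], "not in reference")
  expect_match(reasons[["snp06"]], "frequency differs")
})

test_that("samples below the call-rate threshold are removed", {
  dos <- matrix(rbinom(40 * 10, 2, 0.4), 40, 10)
  dos[1, 1:3] <- NA # 70% call rate < 90%
  geno <- make_geno(dos)
  out <- qc_filter(geno, stats_for(geno), ref_for(geno))
  expect_false("s1" %in% rownames(out$geno$dosages))
  expect_true("s1" %in% out$report$item[out$report$type == "sample"])
})

test_that("allele harmonization handles swaps and strand flips", {
  set.seed(10)
  dos <- matrix(rbinom(200 * 3, 2, 0.3), 200, 3)
  geno <- make_geno(dos, ref = c("A", "A", "A"), alt = c("G", "G", "G"))
  stats <- stats_for(geno, beta = c(0.5, 0.5, 0.5))
  stats$A1 <- c("G", "A", "C") # matching; swapped; strand-flipped (G -> C)
  stats$A2 <- c("A", "G", "T")
  stats$FREQ <- c(0.3, 0.7, 0.3)
  out <- qc_filter(geno, stats, ref_for(geno))
  expect_equal(out$stats$BETA, c(0.5, -0.5, 0.5))
  expect_equal(out$stats$FREQ, c(0.3, 0.3, 0.3))
  expect_equal(out$stats$A1, rep("G", 3)) # all now on the ALT allele

  # unresolvable coding is dropped with a reason
  stats$A1[2] <- "C"; stats$A2[2] <- "A" # neither match nor flip for A/G SNP
  out2 <- qc_filter(geno, stats, ref_for(geno))
  expect_false("snp02" %in% out2$stats$SNP)
  expect_true(any(out2$report$reason == "unresolvable allele coding"))
})

test_that("flipping input allele labels and negating beta leaves scores unchanged", {
  set.seed(11)
  cfg <- sim_config(n_subjects = 150, n_snps = 60, n_causal = 10, seed = 12)
  g <- simulate_genotypes(cfg)
  amb <- topicprs:::is_ambiguous_pair(g$geno$variants$ref, g$geno$variants$alt)
  q1 <- qc_filter(g$geno, g$stats, g$ref)
  flipped <- g$stats
  flipped$A1 <- g$stats$A2
  flipped$A2 <- g$stats$A1
  flipped$BETA <- -g$stats$BETA
  flipped$FREQ <- 1 - g$stats$FREQ
  q2 <- qc_filter(g$geno, flipped, g$ref)
  s1 <- score_prs(q1$geno, q1$stats, config = prs_config())
  s2 <- score_prs(q2$geno, q2$stats, config = prs_config())
  expect_equal(s1$raw_scores, s2$raw_scores, tolerance = 1e-12)
})

test_that("an empty surviving panel raises EmptyPanelError", {
  dos <- matrix(rbinom(50 * 2, 2, 0.5), 50, 2)
  geno <- make_geno(dos, ref = c("A", "C"), alt = c("T", "G"))
  ref <- ref_for(geno)
  ref <- ref[0, ] # nothing in the panel
  expect_error(qc_filter(geno, stats_for(geno), ref), "EmptyPanelError")
})

# clumping --------------------------------------------------------------------

test_that("clumping keeps the stronger of two correlated nearby SNPs", {
  set.seed(12)
  x <- rbinom(400, 2, 0.4)
  y <- ifelse(runif(400) < 0.95, x, rbinom(400, 2, 0.4)) # r2 well above 0.5
  geno <- make_geno(cbind(x, y), pos = c(100000L, 200000L))
  stats <- stats_for(geno, p = c(1e-4, 1e-8))
  kept <- ld_clump(stats, geno, prs_config())
  expect_equal(kept, "snp02") # the p = 1e-8 SNP wins

  # same pair on different chromosomes: both retained
  geno2 <- make_geno(cbind(x, y), chrom = c(1L, 2L), pos = c(100000L, 200000L))
  kept2 <- ld_clump(stats_for(geno2, p = c(1e-4, 1e-8)), geno2, prs_config())
  expect_setequal(kept2, c("snp01", "snp02"))

  # outside the 250 kb window: both retained
  geno3 <- make_geno(cbind(x, y), pos = c(100000L, 400000L))
  kept3 <- ld_clump(stats_for(geno3, p = c(1e-4, 1e-8)), geno3, prs_config())
  expect_setequal(kept3, c("snp01", "snp02"))
})

test_that("clumping equals the naive greedy oracle and ignores row order", {
  for (seed in 1:30) {
    g <- random_clump_instance(seed)
    cfg <- prs_config()
    kept <- ld_clump(g$stats, g$geno, cfg)
    want <- oracle_clump(g$stats, g$geno, cfg$clump_window_kb * 1000,
                         cfg$clump_r2)
    expect_equal(sort(kept), sort(want))
    shuffled <- g$stats[sample(nrow(g$stats)), ]
    expect_setequal(ld_clump(shuffled, g$geno, cfg), kept)
  }
})

# scoring ---------------------------------------------------------------------

test_that("tranche scores reproduce the worked 3-SNP example", {
  dos <- rbind(c(2, 1, 0), c(0, 1, 2))
  geno <- make_geno(dos)
  stats <- stats_for(geno, beta = c(0.2, -0.1, 0.05), p = rep(1e-9, 3))
  prof <- score_prs(geno, stats, config = prs_config())
  expect_equal(unname(prof$raw_scores["s1", "S2"]), 0.3, tolerance = 1e-12)
  expect_equal(unname(prof$raw_scores["s1", "S8"]), 0.3, tolerance = 1e-12)

  zero <- score_prs(geno, stats_for(geno, beta = rep(0, 3), p = rep(1e-9, 3)),
                    config = prs_config())
  expect_true(all(zero$raw_scores == 0))
})

test_that("a SNP enters exactly the tranches whose ceiling covers its p", {
  dos <- matrix(rbinom(100, 2, 0.5), 100, 1)
  geno <- make_geno(dos)
  stats <- stats_for(geno, p = 5e-4)
  prof <- score_prs(geno, stats, config = prs_config())
  expect_equal(unname(prof$n_snps), c(1L, 1L, 0L, 0L, 0L, 0L, 0L))
  expect_true(all(c("S4", "S5", "S6", "S7", "S8") %in% prof$degenerate))
})

test_that("tranche SNP sets are nested and standardized scores are unit scale", {
  cfg <- sim_config(n_subjects = 300, n_snps = 300, n_causal = 30, seed = 13)
  g <- simulate_genotypes(cfg)
  q <- qc_filter(g$geno, g$stats, g$ref)
  kept <- ld_clump(q$stats, q$geno)
  prof <- score_prs(q$geno, q$stats, kept)
  labels <- names(prs_config()$tranches)
  for (i in seq_len(length(labels) - 1)) {
    expect_true(all(prof$snps[[labels[i + 1]]] %in% prof$snps[[labels[i]]]))
  }
  for (lab in labels) {
    if (lab %in% prof$degenerate) next
    expect_equal(mean(prof$scores[, lab]), 0, tolerance = 1e-10)
    expect_equal(sd(prof$scores[, lab]), 1, tolerance = 1e-10)
  }
})

test_that("missing dosages are imputed at twice the sample allele frequency", {
  dos <- rbind(c(2, NA), c(0, 2), c(2, 0), c(0, 2))
  geno <- make_geno(dos)
  stats <- stats_for(geno, beta = c(0, 1), p = rep(1e-9, 2))
  prof <- score_prs(geno, stats, config = prs_config())
  # observed mean dosage of snp02 is 4/3
  expect_equal(unname(prof$raw_scores["s1", "S2"]), 4 / 3, tolerance = 1e-12)
})

# PCA -------------------------------------------------------------------------

test_that("genotype PCs are orthonormal and separate divergent populations", {
  set.seed(14)
  n <- 250
  m <- 400
  pop <- rep(0:1, each = n / 2)
  f1 <- runif(m, 0.1, 0.9)
  shift <- pmin(0.95, pmax(0.05, f1 + sample(c(-1, 1), m, TRUE) * 0.25))
  dos <- t(vapply(seq_len(n), function(i) {
    rbinom(m, 2, if (pop[i] == 0) f1 else shift)
  }, numeric(m)))
  geno <- make_geno(dos, pos = seq_len(m) * 1000L)
  pcs <- genotype_pca(geno, 5)
  expect_equal(crossprod(pcs), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_gt(abs(cor(pcs[, 1], pop)), 0.9)
})

test_that("degenerate and undersized PCA inputs raise errors", {
  dos <- matrix(1, 10, 20) # identical subjects, monomorphic
  expect_error(genotype_pca(make_geno(dos), 5), "polymorphic|degenerate")
  dos2 <- matrix(rep(rbinom(20, 2, 0.5), each = 3), 3, 20) # 3 subjects
  expect_error(genotype_pca(make_geno(dos2), 5), "fewer subjects")
  # identical rows but polymorphic columns: no variance across subjects
  dos3 <- matrix(rep(rbinom(20, 1, 0.5), each = 10), 10, 20)
  expect_error(genotype_pca(make_geno(dos3), 5), "degenerate|polymorphic")
})

test_that("QC report accounts for every dropped and surviving item", {
  set.seed(15)
  cfg <- sim_config(n_subjects = 120, n_snps = 80, n_causal = 10, seed = 16)
  g <- simulate_genotypes(cfg)
  out <- qc_filter(g$geno, g$stats, g$ref)
  snp_drops <- sum(out$report$type == "snp")
  expect_equal(snp_drops + ncol(out$geno$dosages), cfg$n_snps)
  sample_drops <- sum(out$report$type == "sample")
  expect_equal(sample_drops + nrow(out$geno$dosages), cfg$n_subjects)
})
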