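#' Pipeline run configuration
#'
#' Collects input paths and stage options for [run_all()]. All referenced
#' paths are checked at construction time. One global seed deterministically
#' derives per-stage seeds, so any stage is independently reproducible.
#'
#' @param phenotypes CSV path (first column subject id) of the clinical
#'   feature table.
#' @param feature_kinds named character vector mapping features to
#'   binary/categorical/continuous.
#' @param vcf genotype VCF path.
#' @param sumstats named character vector, trait label -> summary-stat TSV.
#' @param ref_panel reference allele-frequency TSV path.
#' @param covariates optional CSV path (first column subject id) of non-genetic
#'   covariates such as age and sex.
#' @param gene_lists optional named character vector, trait -> gene-list path.
#' @param overrides,name_map pseudo-EMR options (see [binarize_features()],
#'   [build_documents()]).
#' @param n_topics fixed topic count; ignored when `candidate_K` is given.
#' @param candidate_K optional grid for [select_num_topics()].
#' @param lda an [lda_config()] template (n_topics overridden).
#' @param prs a [prs_config()].
#' @param n_pcs number of genotype principal components used as covariates.
#' @param exclude_topics topic indices excluded from the association scan.
#' @param gene_universe universe size for the overlap test.
#' @param out_dir output directory (created if needed).
#' @param seed global seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(phenotypes, feature_kinds, vcf, sumstats, ref_panel,
                       covariates = NULL, gene_lists = NULL, overrides = NULL,
                       name_map = NULL, n_topics = NULL, candidate_K = NULL,
                       lda = lda_config(2L), prs = prs_config(), n_pcs = 5L,
                       exclude_topics = NULL, gene_universe = 20000L,
                       out_dir, seed = 1L) {
  paths <- c(phenotypes, vcf, unname(sumstats), ref_panel,
             covariates, unname(gene_lists))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input path(s) do not exist: ", paste(missing, collapse = ", "))
  }
  if (is.null(n_topics) && is.null(candidate_K)) {
    stop("supply n_topics or candidate_K")
  }
  if (is.null(names(sumstats))) stop("sumstats must be a named vector (trait -> path)")
  structure(list(phenotypes = phenotypes, feature_kinds = feature_kinds,
                 vcf = vcf, sumstats = sumstats, ref_panel = ref_panel,
                 covariates = covariates, gene_lists = gene_lists,
                 overrides = overrides, name_map = name_map,
                 n_topics = n_topics, candidate_K = candidate_K, lda = lda,
                 prs = prs, n_pcs = n_pcs, exclude_topics = exclude_topics,
                 gene_universe = gene_universe, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Stage order: pseudo-EMR construction, topic modelling (with topic-number
#' selection unless fixed), per-trait genetics (QC, clumping, tranche PRS),
#' genotype PCA, topic-PRS association scan, gene-list overlap. All stage
#' outputs are written under `cfg$out_dir` as plain text, together with a JSON
#' run manifest recording versions, seeds, input checksums and per-stage
#' counts.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) a list with all stage objects plus the `manifest`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(...) file.path(cfg$out_dir, ...)

  corp <- stage("pseudo_emr", {
    ft <- read_feature_table(cfg$phenotypes, kinds = cfg$feature_kinds,
                             overrides = cfg$overrides)
    corp <- make_pseudo_emr(ft, name_map = cfg$name_map)
    write_corpus(corp, outp("corpus.txt"), outp("vocabulary.txt"))
    excl <- attr(attr(corp, "feature_table"), "exclusion_log")
    write.table(excl, outp("excluded_features.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    corp
  })

  diag <- NULL
  K <- cfg$n_topics
  if (!is.null(cfg$candidate_K)) {
    diag <- stage("select_k", select_num_topics(
      corp, cfg$candidate_K, config = cfg$lda,
      seed = derive_seed(cfg$seed, "select-k")))
    K <- diag$selected_K
    write.table(diag$metrics, outp("topic_diagnostics.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }

  model <- stage("topic_model", {
    lcfg <- cfg$lda
    lcfg$n_topics <- as.integer(K)
    lcfg$seed <- derive_seed(cfg$seed, "lda")
    m <- fit_lda(corp, lcfg)
    write.table(m$phi, outp("phi.tsv"), sep = "\t", quote = FALSE)
    write.table(m$theta, outp("theta.tsv"), sep = "\t", quote = FALSE)
    write.table(top_terms(m), outp("top_terms.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    m
  })

  geno <- stage("read_genotypes", read_vcf(cfg$vcf))
  ref <- stage("read_ref_panel", read_ref_panel(cfg$ref_panel))
  profiles <- list()
  geno_qc <- NULL
  for (trait in names(cfg$sumstats)) {
    profiles[[trait]] <- stage(paste0("genetics_", trait), {
      stats <- read_sumstats(cfg$sumstats[[trait]])
      qc <- qc_filter(geno, stats, ref, cfg$prs)
      if (is.null(geno_qc)) geno_qc <- qc$geno
      write.table(qc$report, outp(sprintf("qc_report_%s.tsv", trait)),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      retained <- ld_clump(qc$stats, qc$geno, cfg$prs)
      writeLines(retained, outp(sprintf("retained_snps_%s.txt", trait)))
      prof <- score_prs(qc$geno, qc$stats, retained, cfg$prs, trait = trait)
      write.table(prof$scores, outp(sprintf("prs_%s.tsv", trait)),
                  sep = "\t", quote = FALSE)
      prof
    })
  }

  pcs <- stage("pca", genotype_pca(geno_qc, cfg$n_pcs))
  write.table(pcs, outp("genotype_pcs.tsv"), sep = "\t", quote = FALSE)

  scan <- stage("association", {
    ids <- intersect(rownames(model$theta), rownames(pcs))
    if (!length(ids)) stop("no subjects shared between corpus and genotypes")
    covars <- as.data.frame(pcs[ids, , drop = FALSE])
    if (!is.null(cfg$covariates)) {
      cv <- read.table(cfg$covariates, sep = ",", header = TRUE,
                       check.names = FALSE, stringsAsFactors = FALSE)
      rownames(cv) <- as.character(cv[[1L]])
      covars <- cbind(cv[ids, -1L, drop = FALSE], covars)
    }
    profs <- lapply(profiles, function(p) {
      p$scores <- p$scores[ids, , drop = FALSE]
      p
    })
    sc <- association_scan(model$theta[ids, , drop = FALSE], profs, covars,
                           exclude_topics = cfg$exclude_topics)
    write.table(sc$table, outp("associations.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    for (trait in names(sc$neglog10p)) {
      write.table(sc$neglog10p[[trait]],
                  outp(sprintf("assoc_matrix_%s.tsv", trait)),
                  sep = "\t", quote = FALSE)
    }
    sc
  })

  overlap <- NULL
  if (!is.null(cfg$gene_lists) && length(cfg$gene_lists) >= 2L) {
    overlap <- stage("overlap", {
      sets <- lapply(names(cfg$gene_lists), function(tr) {
        read_gene_list(cfg$gene_lists[[tr]], trait = tr)
      })
      ot <- overlap_table(sets, cfg$gene_universe)
      write.table(ot, outp("gene_overlap.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      ot
    })
  }

  manifest <- list(
    package = "topicprs",
    package_version = as.character(utils::packageVersion("topicprs")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    inputs = {
      paths <- c(cfg$phenotypes, cfg$vcf, unname(cfg$sumstats), cfg$ref_panel)
      setNames(as.list(unname(tools::md5sum(paths))), basename(paths))
    },
    counts = list(
      n_documents = length(corp$documents),
      vocabulary = length(corp$vocabulary),
      n_topics = as.integer(K),
      selected_by_grid = !is.null(cfg$candidate_K),
      n_snps_post_qc = ncol(geno_qc$dosages),
      snps_per_tranche = lapply(profiles, function(p) as.list(p$n_snps)),
      n_association_tests = nrow(scan$table)
    )
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(corpus = corp, diagnostics = diag, model = model,
                 profiles = profiles, pcs = pcs, scan = scan,
                 overlap = overlap, manifest = manifest))
}

#' Simulate a synthetic study and run the full pipeline on it
#'
#' Generates genotypes/GWAS/reference panel and a pseudo-EMR corpus with a
#' planted polygenic effect on one topic, writes all inputs to disk in the
#' standard formats, runs [run_all()] on them, and reports truth-versus-
#' estimate comparisons: permutation-matched total-variation distances between
#' estimated and true topics, the correlation between true burden and each
#' tranche score, and whether the planted (topic, trait) cell is the top hit
#' of the association grid.
#'
#' @param sim_cfg a [sim_config()].
#' @param out_dir output directory.
#' @param lda an [lda_config()] template.
#' @param candidate_K optional grid for topic-number selection; default fixes
#'   K at the generating value.
#' @param n_null_traits additional unlinked GWAS traits to scan.
#' @param covariate_age_sex simulate and adjust for independent age/sex
#'   covariates.
#' @return list with `pipeline` ([run_all()] output) and `report`.
#' @export
simulate_and_run <- function(sim_cfg, out_dir,
                             lda = lda_config(2L, n_iter = 600L,
                                              burn_in = 300L, thin = 30L),
                             candidate_K = NULL, n_null_traits = 1L,
                             covariate_age_sex = TRUE) {
  stopifnot(inherits(sim_cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- function(...) file.path(out_dir, "inputs", ...)
  dir.create(inp(), showWarnings = FALSE, recursive = TRUE)

  g <- simulate_genotypes(sim_cfg, n_null_traits = n_null_traits)
  base <- simulate_corpus(sim_cfg)
  linked <- link_prs_to_topic(base$truth$theta_true, g$truth$true_burden,
                              sim_cfg, base$truth$phi_true)

  write_vcf(g$geno, inp("genotypes.vcf"))
  write_ref_panel(g$ref, inp("ref_panel.tsv"))
  sumstats <- c(trait1 = inp("sumstats_trait1.tsv"))
  write_sumstats(g$stats, sumstats[[1]])
  for (nm in names(g$null_stats)) {
    p <- inp(sprintf("sumstats_%s.tsv", nm))
    write_sumstats(g$null_stats[[nm]], p)
    sumstats[nm] <- p
  }
  write_feature_table(linked$feature_table, inp("phenotypes.csv"))
  write_truth(c(linked$truth, g$truth["causal_effects"]), inp("truth.json"))

  cov_path <- NULL
  if (covariate_age_sex) {
    set.seed(derive_seed(sim_cfg$seed, "covariates"))
    cv <- data.frame(subject_id = subject_ids(sim_cfg$n_subjects),
                     age = round(runif(sim_cfg$n_subjects, 4, 18), 1),
                     sex = rbinom(sim_cfg$n_subjects, 1, 0.5))
    write.table(cv, inp("covariates.csv"), sep = ",", row.names = FALSE,
                quote = FALSE)
    cov_path <- inp("covariates.csv")
  }

  terms <- term_names(sim_cfg$vocab_size)
  cfg <- run_config(
    phenotypes = inp("phenotypes.csv"),
    feature_kinds = setNames(rep("binary", length(terms)), terms),
    vcf = inp("genotypes.vcf"), sumstats = sumstats,
    ref_panel = inp("ref_panel.tsv"), covariates = cov_path,
    n_topics = if (is.null(candidate_K)) sim_cfg$n_topics_true else NULL,
    candidate_K = candidate_K, lda = lda, out_dir = out_dir,
    seed = sim_cfg$seed)
  res <- run_all(cfg)

  # truth-versus-estimate report
  # compare on the fitted vocabulary (sparsity filtering can drop rare terms);
  # restrict the true topics to those terms and renormalise
  phi_ref <- linked$truth$phi_true[, match(colnames(res$model$phi), terms),
                                   drop = FALSE]
  phi_ref <- phi_ref / rowSums(phi_ref)
  mt <- match_topics(res$model$phi, phi_ref)
  scored_ids <- rownames(res$profiles[["trait1"]]$scores)
  burden <- g$truth$true_burden[match(scored_ids, rownames(g$geno$dosages))]
  prs_cor <- apply(res$profiles[["trait1"]]$scores, 2L,
                   function(s) if (sd(s) > 0) cor(burden, s) else NA_real_)
  tab <- res$scan$table
  top <- tab[which.min(tab$p), ]
  matched_target <- which(mt$perm == sim_cfg$target_topic)
  planted <- tab[tab$topic == matched_target & tab$trait == "trait1", ]
  report <- list(
    topic_matching = list(perm = mt$perm, tv = mt$tv, mean_tv = mt$mean_tv),
    prs_burden_correlation = as.list(prs_cor),
    planted_effect = list(
      target_topic_true = sim_cfg$target_topic,
      target_topic_fitted = matched_target,
      top_hit = list(topic = top$topic, trait = top$trait,
                     tranche = top$tranche, p = top$p),
      top_hit_is_planted = (top$topic == matched_target &&
                              top$trait == "trait1"),
      min_p_planted_cell = min(planted$p, na.rm = TRUE),
      best_tranche = planted$tranche[which.min(planted$p)],
      sr2_best = planted$sr2[which.min(planted$p)]
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "truth_vs_estimate.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(pipeline = res, report = report, truth = linked$truth,
       geno_truth = g$truth)
}
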