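#' Write / read a pseudo-EMR corpus
#'
#' The corpus is stored as one document per line (space-separated tokens),
#' with the subject id as the first field, plus a vocabulary file (one term
#' per line).
#'
#' @param corpus a `corpus`.
#' @param docs_file,vocab_file output paths.
#' @return (write) the paths, invisibly; (read) a `corpus`.
#' @export
write_corpus <- function(corpus, docs_file, vocab_file) {
  lines <- vapply(seq_along(corpus$documents), function(i) {
    paste(c(corpus$doc_subject_map[i], corpus$documents[[i]]), collapse = " ")
  }, character(1))
  writeLines(lines, docs_file)
  writeLines(corpus$vocabulary, vocab_file)
  invisible(c(docs_file, vocab_file))
}

#' @rdname write_corpus
#' @export
read_corpus <- function(docs_file, vocab_file) {
  lines <- readLines(docs_file)
  parts <- strsplit(lines, " ", fixed = TRUE)
  new_corpus(documents = lapply(parts, function(p) p[-1L]),
             vocabulary = readLines(vocab_file),
             doc_subject_map = vapply(parts, `[`, character(1), 1L))
}

#' Write / read a feature table as CSV
#'
#' First column is the subject id; remaining columns are features. Feature
#' kinds are supplied on read (they are not inferable from values alone).
#'
#' @param ft a [feature_table()].
#' @param path CSV path.
#' @param kinds,overrides see [feature_table()].
#' @export
write_feature_table <- function(ft, path) {
  df <- cbind(subject_id = ft$subject_ids, ft$data)
  write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, kinds, overrides = NULL) {
  df <- read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  feature_table(df[, -1L, drop = FALSE], subject_ids = df[[1L]],
                kinds = kinds, overrides = overrides)
}

#' Write / read GWAS summary statistics
#'
#' Tab-separated with header `SNP CHR BP A1 A2 BETA FREQ P` (A1 = effect
#' allele, FREQ = effect-allele frequency). Odds ratios are converted to log
#' odds on read with `or = TRUE`.
#'
#' @param stats summary-statistics data.frame.
#' @param path TSV path.
#' @param or if TRUE the BETA column holds odds ratios and is log-transformed.
#' @export
write_sumstats <- function(stats, path) {
  cols <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "FREQ", "P")
  stopifnot(all(cols %in% names(stats)))
  write.table(format(stats[cols], digits = 17, trim = TRUE, scientific = NA),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path, or = FALSE) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("SNP", "CHR", "BP", "A1", "A2", "BETA", "FREQ", "P") %in% names(df)))
  if (or) df$BETA <- log(df$BETA)
  if (any(df$P <= 0 | df$P > 1)) stop("p-values must lie in (0, 1]")
  df
}

#' Write / read a reference allele-frequency panel
#'
#' Tab-separated with header `SNP CHR BP A1 A2 FREQ` (FREQ = A1 frequency).
#'
#' @param ref reference-panel data.frame.
#' @param path TSV path.
#' @export
write_ref_panel <- function(ref, path) {
  cols <- c("SNP", "CHR", "BP", "A1", "A2", "FREQ")
  stopifnot(all(cols %in% names(ref)))
  write.table(format(ref[cols], digits = 17, trim = TRUE, scientific = NA),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ref_panel
#' @export
read_ref_panel <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("SNP", "A1", "A2", "FREQ") %in% names(df)))
  df
}

#' Write a genotype matrix as VCF v4.2
#'
#' Integer dosages are written as GT calls (0/0, 0/1, 1/1, ./.); fractional
#' dosages are written with a DS FORMAT field instead.
#'
#' @param geno a [genotype_matrix()].
#' @param path output `.vcf` path (plain text).
#' @export
write_vcf <- function(geno, path) {
  dos <- geno$dosages
  v <- geno$variants
  integral <- all(is.na(dos) | dos == round(dos))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=topicprs",
               if (integral)
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
               else
                 '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(dos)), collapse = "\t")), con)
  fmt <- if (integral) "GT" else "DS"
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(j) {
    d <- dos[, j]
    field <- if (integral) {
      ifelse(is.na(d), "./.", gt_code[d + 1L])
    } else {
      ifelse(is.na(d), ".", format(d, digits = 17, trim = TRUE))
    }
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
            ".", fmt, field), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Accepts GT (hard calls, counted on the ALT allele) or DS (dosage) FORMAT
#' fields; multiallelic records are rejected.
#'
#' @param path VCF path.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fx$ALT, fixed = TRUE))) stop("multiallelic records not supported")
  fmt_keys <- unique(vcf@gt[, "FORMAT"])
  use_ds <- all(grepl("\\bDS\\b", fmt_keys))
  if (use_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    lut <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
    ds <- matrix(unname(lut[chartr("|", "/", gt)]), nrow(gt), ncol(gt),
                 dimnames = dimnames(gt))
    unknown <- !is.na(gt) & is.na(ds) & chartr("|", "/", gt) != "./."
    if (any(unknown)) stop("unsupported GT code(s): ",
                           paste(unique(gt[unknown]), collapse = ", "))
  }
  variants <- data.frame(id = fx$ID, chrom = fx$CHROM,
                         pos = as.integer(fx$POS), ref = fx$REF, alt = fx$ALT,
                         stringsAsFactors = FALSE)
  genotype_matrix(t(ds), variants)
}

#' Read a gene list (one symbol per line)
#'
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path text file path.
#' @param trait trait label (default: file name without extension).
#' @return a [gene_set()].
#' @export
read_gene_list <- function(path, trait = sub("\\.[^.]*$", "", basename(path))) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_set(trait, lines)
}

#' @rdname read_gene_list
#' @param genes character vector of symbols to write.
#' @export
write_gene_list <- function(genes, path) {
  if (inherits(genes, "gene_set")) genes <- genes$genes
  writeLines(genes, path)
  invisible(path)
}
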