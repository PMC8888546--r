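#' Construct a feature table
#'
#' A feature table holds one row per subject and one clinical feature per
#' column, with a declared kind (`binary`, `categorical`, `continuous`) for
#' every column and optional fixed dichotomization thresholds for continuous
#' features whose cut-points come from clinical literature rather than from
#' the data.
#'
#' @param data data.frame of feature values, one row per subject. Binary
#'   features must be coded 0/1 (NA allowed).
#' @param subject_ids character vector of unique subject identifiers.
#' @param kinds named character vector mapping every column of `data` to one
#'   of `"binary"`, `"categorical"`, `"continuous"`.
#' @param overrides optional named list; each entry is
#'   `list(cut = <numeric>, direction = "above"|"below")` keyed by feature
#'   name, fixing that feature's presence threshold.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(data, subject_ids = rownames(data), kinds,
                          overrides = NULL) {
  data <- as.data.frame(data)
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(nrow(data)))
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  if (length(subject_ids) != nrow(data)) stop("subject_ids/data length mismatch")
  missing_kind <- setdiff(names(data), names(kinds))
  if (length(missing_kind)) {
    stop("no kind declared for feature(s): ", paste(missing_kind, collapse = ", "))
  }
  kinds <- kinds[names(data)]
  bad <- !kinds %in% c("binary", "categorical", "continuous")
  if (any(bad)) stop("unknown feature kind(s): ", paste(unique(kinds[bad]), collapse = ", "))
  structure(
    list(data = data, subject_ids = subject_ids, kinds = kinds,
         overrides = overrides, binarized = all(kinds == "binary")),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d subjects x %d features (%s)\n",
              length(x$subject_ids), ncol(x$data),
              if (isTRUE(x$binarized)) "binarized" else
                paste(table(x$kinds), names(table(x$kinds)), collapse = ", ")))
  invisible(x)
}

#' Exact 1-D two-means dichotomization
#'
#' Splits a continuous vector into two clusters minimising the within-cluster
#' sum of squares. In one dimension the optimal 2-means partition is an
#' interval split of the sorted values, so the optimum is found exactly by
#' scanning all n-1 split points of the sorted non-missing values; no
#' iterative (Lloyd) step or random initialization is involved. The
#' higher-mean cluster is labelled 1 ("present"); missing values stay missing.
#'
#' @param values numeric vector, NA allowed.
#' @return list with `labels` (integer 0/1 vector, NA preserved) and
#'   `cut_point` (midpoint between the two boundary values).
#' @export
dichotomize_kmeans <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2L || length(unique(obs)) < 2L) {
    stop("ZeroVarianceFeature: need >= 2 distinct non-missing values")
  }
  s <- sort(obs)
  n <- length(s)
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  tot <- cs[n]
  # WCSS of the split after position i: lower cluster s[1..i], upper s[(i+1)..n]
  i <- seq_len(n - 1L)
  wcss_lo <- cs2[i] - cs[i]^2 / i
  wcss_hi <- (cs2[n] - cs2[i]) - (tot - cs[i])^2 / (n - i)
  best <- which.min(wcss_lo + wcss_hi)
  cut_point <- (s[best] + s[best + 1L]) / 2
  labels <- ifelse(is.na(values), NA_integer_, as.integer(values > s[best]))
  list(labels = labels, cut_point = cut_point)
}

#' Dichotomize by a fixed clinical threshold
#'
#' Overrides data-driven dichotomization for features whose cut-point is taken
#' from clinical literature (e.g. developmental-delay thresholds).
#'
#' @param values numeric vector, NA allowed.
#' @param override list with `cut` (numeric) and `direction` (`"above"` means
#'   values strictly greater than `cut` are present; `"below"` means values
#'   strictly less than `cut` are present).
#' @return integer 0/1 vector, NA preserved.
#' @export
apply_threshold_override <- function(values, override) {
  if (is.null(override$cut) || is.null(override$direction)) {
    stop("override must supply both 'cut' and 'direction'")
  }
  if (!override$direction %in% c("above", "below")) {
    stop("direction must be 'above' or 'below'")
  }
  present <- if (override$direction == "above") values > override$cut
             else values < override$cut
  ifelse(is.na(values), NA_integer_, as.integer(present))
}

#' Binarize all features of a table
#'
#' Binary features are validated; categorical features are expanded to one
#' indicator per level (`feature.level`); continuous features are dichotomized
#' by [dichotomize_kmeans()] unless a fixed threshold override is supplied.
#' Features with fewer than two distinct non-missing values are excluded and
#' logged.
#'
#' @param ft a [feature_table()].
#' @return a binarized `feature_table` with an `exclusion_log` attribute
#'   (data.frame: feature, reason) and a `cut_points` attribute.
#' @export
binarize_features <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  out <- list()
  log <- data.frame(feature = character(), reason = character())
  cuts <- list()
  for (nm in names(ft$data)) {
    v <- ft$data[[nm]]
    kind <- ft$kinds[[nm]]
    if (kind == "binary") {
      if (!all(v %in% c(0, 1, NA))) stop("binary feature not coded 0/1: ", nm)
      out[[nm]] <- as.integer(v)
    } else if (kind == "categorical") {
      lev <- sort(unique(as.character(v[!is.na(v)])))
      if (length(lev) < 2L) {
        log <- rbind(log, data.frame(feature = nm, reason = "zero variance"))
        next
      }
      for (l in lev) {
        out[[paste(nm, l, sep = ".")]] <-
          ifelse(is.na(v), NA_integer_, as.integer(as.character(v) == l))
      }
    } else { # continuous
      ov <- ft$overrides[[nm]]
      if (!is.null(ov)) {
        out[[nm]] <- apply_threshold_override(v, ov)
        cuts[[nm]] <- ov$cut
      } else {
        res <- tryCatch(dichotomize_kmeans(v), error = function(e) e)
        if (inherits(res, "error")) {
          log <- rbind(log, data.frame(feature = nm, reason = "zero variance"))
          next
        }
        out[[nm]] <- res$labels
        cuts[[nm]] <- res$cut_point
      }
    }
  }
  if (!length(out)) stop("no features survived binarization")
  data <- as.data.frame(out, check.names = FALSE)
  ft2 <- feature_table(data, ft$subject_ids,
                       kinds = setNames(rep("binary", ncol(data)), names(data)))
  ft2$binarized <- TRUE
  attr(ft2, "exclusion_log") <- log
  attr(ft2, "cut_points") <- cuts
  ft2
}

#' Drop prohibitively sparse features
#'
#' Removes binarized features whose presence count across subjects is less
#' than or equal to `min_count - 1` (default rule: count <= 1 removed).
#'
#' @param ft a binarized [feature_table()].
#' @param max_sparse_count features with presence count `<= max_sparse_count`
#'   are removed (default 1).
#' @return filtered `feature_table`; removed features recorded in the
#'   `exclusion_log` attribute.
#' @export
filter_sparse_features <- function(ft, max_sparse_count = 1L) {
  stopifnot(inherits(ft, "feature_table"), isTRUE(ft$binarized))
  counts <- vapply(ft$data, function(v) sum(v == 1L, na.rm = TRUE), integer(1))
  drop <- names(counts)[counts <= max_sparse_count]
  keep <- setdiff(names(counts), drop)
  if (!length(keep)) stop("all features removed by sparsity filter")
  ft2 <- feature_table(ft$data[keep], ft$subject_ids,
                       kinds = ft$kinds[keep])
  ft2$binarized <- TRUE
  prev <- attr(ft, "exclusion_log") %||% data.frame(feature = character(), reason = character())
  attr(ft2, "exclusion_log") <-
    rbind(prev, data.frame(feature = drop,
                           reason = rep("sparse (count <= 1)", length(drop))))
  attr(ft2, "cut_points") <- attr(ft, "cut_points")
  ft2
}

#' Build pseudo-EMR documents from a binarized feature table
#'
#' Each subject's document is the list of term labels for their present
#' features. The default term label is the feature name lowercased with
#' whitespace replaced by hyphens (complex clinical descriptions are coerced
#' into single tokens); `name_map` entries override the default label.
#' Subjects with no present features yield no document and are logged with a
#' warning. A missing value contributes no token.
#'
#' @param ft a binarized, filtered [feature_table()].
#' @param name_map optional named character vector `c("feature name" = "term")`.
#' @return an object of class `corpus`: `documents` (list of character token
#'   vectors), `vocabulary` (ordered unique terms), `doc_subject_map`.
#' @export
build_documents <- function(ft, name_map = NULL) {
  stopifnot(inherits(ft, "feature_table"), isTRUE(ft$binarized))
  terms <- vapply(names(ft$data), function(nm) {
    if (!is.null(name_map) && nm %in% names(name_map)) unname(name_map[[nm]])
    else gsub("\\s+", "-", tolower(trimws(nm)))
  }, character(1))
  if (anyDuplicated(terms)) {
    dup <- unique(terms[duplicated(terms)])
    stop("TermCollision: features map to duplicate terms: ",
         paste(dup, collapse = ", "))
  }
  mat <- as.matrix(ft$data) == 1L
  mat[is.na(mat)] <- FALSE
  docs <- apply(mat, 1L, function(row) unname(terms[row]), simplify = FALSE)
  nonempty <- lengths(docs) > 0L
  if (any(!nonempty)) {
    warning(sum(!nonempty), " subject(s) with no present features dropped: ",
            paste(head(ft$subject_ids[!nonempty], 5L), collapse = ", "))
  }
  docs <- docs[nonempty]
  vocab <- sort(unique(unlist(docs)))
  new_corpus(documents = unname(docs), vocabulary = vocab,
             doc_subject_map = ft$subject_ids[nonempty])
}

new_corpus <- function(documents, vocabulary, doc_subject_map) {
  stopifnot(length(documents) == length(doc_subject_map))
  structure(list(documents = documents, vocabulary = vocabulary,
                 doc_subject_map = doc_subject_map),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("corpus: %d documents, vocabulary of %d terms, %s tokens/doc (mean)\n",
              length(x$documents), length(x$vocabulary),
              format(mean(lengths(x$documents)), digits = 3)))
  invisible(x)
}

#' Full pseudo-EMR construction
#'
#' Convenience wrapper: binarize, filter sparse features, build documents.
#'
#' @inheritParams binarize_features
#' @inheritParams build_documents
#' @inheritParams filter_sparse_features
#' @return a `corpus`; the binarized table is attached as attribute
#'   `feature_table`.
#' @export
make_pseudo_emr <- function(ft, name_map = NULL, max_sparse_count = 1L) {
  bt <- if (isTRUE(ft$binarized)) ft else binarize_features(ft)
  bt <- filter_sparse_features(bt, max_sparse_count = max_sparse_count)
  corp <- build_documents(bt, name_map = name_map)
  attr(corp, "feature_table") <- bt
  corp
}
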