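#' Construct a candidate-gene set
#'
#' Symbols are whitespace-trimmed, uppercased and de-duplicated.
#'
#' @param trait trait label.
#' @param genes character vector of gene symbols.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(trait, genes) {
  genes <- unique(toupper(trimws(as.character(genes))))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("empty gene set")
  structure(list(trait = trait, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$trait, length(x$genes)))
  invisible(x)
}

#' Overlap counts between two gene sets
#'
#' @param a,b [gene_set()] objects.
#' @return list with `n_a`, `n_b`, `n_intersection`, `intersection`.
#' @export
overlap_counts <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  inter <- intersect(a$genes, b$genes)
  list(n_a = length(a$genes), n_b = length(b$genes),
       n_intersection = length(inter), intersection = inter)
}

#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing at least `k_observed` shared elements between two
#' sets of sizes `n_a` and `n_b` drawn without replacement from a universe of
#' `n_universe` genes: `P(X >= k)` with
#' `X ~ Hypergeometric(N = n_universe, K = n_a, n = n_b)`, computed by exact
#' log-space summation of the tail. The observed count is included in the tail
#' (enrichment convention). The universe size must be supplied by the user; a
#' common choice is roughly 20,000 protein-coding genes.
#'
#' @param n_universe universe size N.
#' @param n_a,n_b set sizes.
#' @param k_observed observed intersection size.
#' @return upper-tail p-value.
#' @export
hypergeom_overlap_p <- function(n_universe, n_a, n_b, k_observed) {
  stopifnot(n_universe >= 1, n_a >= 0, n_b >= 0, k_observed >= 0)
  if (n_a > n_universe || n_b > n_universe) {
    stop("set sizes cannot exceed the universe size")
  }
  if (k_observed > min(n_a, n_b)) {
    stop("intersection cannot exceed the smaller set")
  }
  lo <- max(0L, n_a + n_b - n_universe)
  if (k_observed <= lo) return(1)
  ks <- seq(k_observed, min(n_a, n_b))
  logterm <- lchoose(n_a, ks) + lchoose(n_universe - n_a, n_b - ks) -
    lchoose(n_universe, n_b)
  m <- max(logterm)
  min(1, exp(m + log(sum(exp(logterm - m)))))
}

#' Pairwise overlap table for several gene sets
#'
#' @param sets list of [gene_set()] objects.
#' @param n_universe universe size passed to [hypergeom_overlap_p()].
#' @return data.frame with one row per unordered trait pair: trait_a, trait_b,
#'   n_a, n_b, n_intersection, p_hypergeom; attribute `venn` holds per-set and
#'   pairwise counts.
#' @export
overlap_table <- function(sets, n_universe) {
  stopifnot(length(sets) >= 2L)
  rows <- list()
  for (i in seq_len(length(sets) - 1L)) {
    for (j in seq(i + 1L, length(sets))) {
      oc <- overlap_counts(sets[[i]], sets[[j]])
      rows[[length(rows) + 1L]] <- data.frame(
        trait_a = sets[[i]]$trait, trait_b = sets[[j]]$trait,
        n_a = oc$n_a, n_b = oc$n_b, n_intersection = oc$n_intersection,
        p_hypergeom = hypergeom_overlap_p(n_universe, oc$n_a, oc$n_b,
                                          oc$n_intersection))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "venn") <- list(
    set_sizes = setNames(vapply(sets, function(s) length(s$genes), integer(1)),
                         vapply(sets, function(s) s$trait, character(1))),
    pair_intersections = out[, c("trait_a", "trait_b", "n_intersection")])
  out
}
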