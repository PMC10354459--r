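# Over-representation testing of unique-binder sets against user-supplied
# phenotype/annotation gene sets: exact hypergeometric upper tail with
# Benjamini-Hochberg correction. Identifier matching is exact-string after
# case normalization; users supply annotation files already mapped to the
# identifiers used in the screen.

norm_gene <- function(x) toupper(trimws(x))

#' Build an annotation-set collection
#'
#' @param terms Named list: `term_id -> list(name = term_name, genes =
#'   character vector)`. Term gene sets are case-normalized and
#'   intersected with the background, so the invariant `genes %in%
#'   background` holds by construction.
#' @param background Character vector of gene identifiers defining the
#'   statistical universe; must be nonempty. A natural choice is every
#'   protein detected in the experiment (all rows surviving QC), an
#'   alternative is all annotated genes.
#' @return Object of class `annotation_sets`.
#' @export
annotation_sets <- function(terms, background) {
  background <- unique(norm_gene(background))
  background <- background[background != ""]
  if (length(background) == 0) abort_mr("background must be nonempty")
  if (is.null(names(terms)) || anyDuplicated(names(terms))) {
    abort_mr("terms must be a uniquely named list")
  }
  terms <- lapply(terms, function(t) {
    list(name = as.character(t$name),
         genes = intersect(unique(norm_gene(t$genes)), background))
  })
  structure(list(terms = terms, background = background),
            class = "annotation_sets")
}

#' Read GMT-style annotation sets
#'
#' Each line: `term_id TAB term_name TAB gene1 TAB gene2 ...`.
#'
#' @param path GMT file path.
#' @return Named list suitable for [annotation_sets()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_mr("annotation file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  terms <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort_mr("malformed GMT line (need term_id, term_name, >=1 gene): %s", ln)
    }
    terms[[parts[1]]] <- list(name = parts[2], genes = parts[-(1:2)])
  }
  terms
}

#' Read a background gene list (one identifier per line)
#'
#' @param path File path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort_mr("gene list file not found: %s", path)
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Exact hypergeometric upper-tail p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` annotated genes when `n` genes are drawn without replacement
#' from a background of `N` genes of which `K` carry the annotation.
#' Computed exactly (no normal approximation).
#'
#' @param k Observed overlap, `0 <= k <= min(K, n)`.
#' @param K Term size within the background.
#' @param n Query size within the background.
#' @param N Background size.
#' @return p-value in (0, 1].
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(vals != floor(vals)) || any(vals < 0)) {
    abort_mr("k, K, n, N must be nonnegative integers")
  }
  if (K > N || n > N) abort_mr("K and n must not exceed N")
  if (k > min(K, n)) abort_mr("k must not exceed min(K, n)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Nonempty numeric vector of p-values in (0, 1].
#' @return Adjusted values, clipped at 1, monotone non-decreasing in
#'   p-value rank.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) abort_mr("pvalues must be nonempty")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    abort_mr("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation test of a query gene set
#'
#' Maps the query onto the annotation background (genes outside the
#' background are dropped and counted), then tests every term with at
#' least one background gene by the exact hypergeometric upper tail and
#' adjusts across terms with Benjamini-Hochberg.
#'
#' @param query Character vector of gene identifiers.
#' @param annotation An [annotation_sets()] object.
#' @return Data frame sorted by ascending p (ties by `term_id`) with
#'   columns `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p`, `q`. The
#'   attribute `n_dropped` records how many query genes fell outside the
#'   background.
#' @export
enrich <- function(query, annotation) {
  if (!inherits(annotation, "annotation_sets")) {
    abort_mr("annotation must be an annotation_sets object")
  }
  query <- unique(norm_gene(query))
  query <- query[query != ""]
  effective <- intersect(query, annotation$background)
  n_dropped <- length(query) - length(effective)
  if (n_dropped > 0) {
    message(sprintf("enrich: %d query gene(s) outside background dropped", n_dropped))
  }
  if (length(effective) == 0) {
    abort_mr("empty effective query: no query gene is in the background")
  }

  N <- length(annotation$background)
  n <- length(effective)
  keep <- vapply(annotation$terms, function(t) length(t$genes) > 0, logical(1))
  terms <- annotation$terms[keep]
  if (length(terms) == 0) abort_mr("no term has genes in the background")

  K <- vapply(terms, function(t) length(t$genes), integer(1))
  k <- vapply(terms, function(t) length(intersect(t$genes, effective)), integer(1))
  p <- mapply(hypergeometric_upper_tail, k = k, K = K,
              MoreArgs = list(n = n, N = N))
  out <- data.frame(term_id = names(terms),
                    term_name = vapply(terms, function(t) t$name, character(1)),
                    k = k, K = K, n = n, N = N, p = p, q = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}
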