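#' Hypergeometric tail probability for term over-representation
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`:
#' the chance of drawing at least `k` term genes when `n` hits are sampled
#' without replacement from a reference of `N` genes of which `K` carry the
#' term.  The lower tail `P(X <= k)` tests depletion.
#'
#' @param k Observed hits annotated with the term.
#' @param n Number of hit genes.
#' @param K Term size within the reference.
#' @param N Reference size.
#' @param tail `"upper"` (over-representation, default) or `"lower"`.
#' @return Probability in `(0, 1]`.
#' @export
hypergeom_p <- function(k, n, K, N, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > n || n > N || K > N || k > K)
    stop("inconsistent counts: need 0 <= k <= min(n, K), n <= N, K <= N")
  if (tail == "upper")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  else
    stats::phyper(k, K, N - K, n)
}

#' GO-slim term enrichment among screen hits
#'
#' Tests each annotation term for over-representation among hit genes
#' relative to the screenable reference set with the hypergeometric
#' distribution and Benjamini-Hochberg FDR control.  Dubious-ORF genes are
#' removed from both sets, term sizes are counted within the reference (not
#' the genome), and terms annotating fewer than `min_term_size` reference
#' genes are not evaluated.
#'
#' @param hit_genes Character vector of hit gene ids (subset of
#'   `reference_genes`).
#' @param reference_genes Character vector: all genes with a comparable
#'   measurement (e.g. scoreable initial density).
#' @param annotation Data frame with columns `term` and `gene`.
#' @param dubious Character vector of dubious-ORF gene ids to exclude.
#' @param min_term_size Smallest reference term size evaluated.
#' @param q_threshold FDR threshold for the `enriched` flag.
#' @param tail `"upper"` for over-representation (default); `"lower"`
#'   reports depletion instead.
#' @return An object of class `go_enrichment`: a data frame with one row
#'   per evaluated term (`term`, `k`, `K`, `n`, `N`, `p`, `q`, `enriched`),
#'   sorted by `q` then `p`.  Empty (with a warning) when there are no hits
#'   or no evaluable terms.
#' @export
enrich <- function(hit_genes, reference_genes, annotation,
                   dubious = character(), min_term_size = 25,
                   q_threshold = 0.06, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  hit_genes <- unique(hit_genes)
  reference_genes <- unique(reference_genes)
  if (!all(hit_genes %in% reference_genes))
    stop("hit genes must be a subset of the reference set")
  hit_genes <- setdiff(hit_genes, dubious)
  reference_genes <- setdiff(reference_genes, dubious)
  empty <- data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE)
  if (!length(hit_genes)) {
    warning("no hit genes after dubious-ORF exclusion; empty result")
    return(structure(empty, class = c("go_enrichment", "data.frame")))
  }
  N <- length(reference_genes)
  n <- length(hit_genes)
  ann <- annotation[annotation$gene %in% reference_genes, ]
  terms <- split(unique(ann[c("term", "gene")])$gene,
                 unique(ann[c("term", "gene")])$term)
  terms <- terms[vapply(terms, length, integer(1)) >= min_term_size]
  if (!length(terms)) {
    warning("no terms with at least ", min_term_size,
            " reference genes; empty result")
    return(structure(empty, class = c("go_enrichment", "data.frame")))
  }
  res <- do.call(rbind, lapply(names(terms), function(tm) {
    K <- length(terms[[tm]])
    k <- length(intersect(terms[[tm]], hit_genes))
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               p = hypergeom_p(k, n, K, N, tail), stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$enriched <- res$q <= q_threshold
  res <- res[order(res$q, res$p, res$term), ]
  rownames(res) <- NULL
  attr(res, "q_threshold") <- q_threshold
  attr(res, "tail") <- tail
  class(res) <- c("go_enrichment", "data.frame")
  res
}

#' @export
print.go_enrichment <- function(x, ...) {
  cat("Term enrichment (", attr(x, "tail"), " tail): ", sum(x$enriched),
      "/", nrow(x), " terms at q <= ", attr(x, "q_threshold"), "\n", sep = "")
  print.data.frame(x, digits = 3)
  invisible(x)
}
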