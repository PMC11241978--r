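## Gene-set over-representation for differentially edited transcripts:
## exact hypergeometric (Fisher) upper tail and the conservative EASE
## variant (one overlapping gene removed before the tail), with
## Benjamini-Hochberg FDR across terms. The background defaults to the
## caller's choice — typically all genes carrying a retained editing site.

#' Hypergeometric upper-tail probability P(X >= k)
#'
#' `k` list genes in the term, `K` background genes in the term, `n` list
#' size, `N` background size.
#'
#' @param k,K,n,N overlap counts (see description).
#' @return upper-tail probability.
#' @export
fisher_tail <- function(k, K, n, N) {
  if (k < 0 || n > N || K > N || k > n || k > K)
    stopf("fisher_tail: inconsistent counts (k=%d K=%d n=%d N=%d)", k, K, n, N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE score: the hypergeometric tail with one success removed
#'
#' `fisher_tail(max(k - 1, 0), K, n, N)` — DAVID's conservative default
#' over-representation statistic; always >= the Fisher tail, and exactly 1
#' for k = 1.
#'
#' @inheritParams fisher_tail
#' @return EASE probability.
#' @export
ease_score <- function(k, K, n, N) {
  fisher_tail(max(k - 1, 0), K, n, N)
}

#' Gene-set over-representation of a query list
#'
#' One row per term with at least one query gene; both the Fisher tail and
#' the EASE score are reported, ranking and FDR use EASE.
#'
#' @param query query gene symbols (e.g. DEdit transcripts). Genes outside
#'   the background are dropped with a warning.
#' @param background background gene symbols.
#' @param sets gene-set collection (named list, see [read_gmt()]).
#' @param rank_by "ease" (default) or "fisher".
#' @return data.frame with term, term_name, k (enriched), n_query, K
#'   (total in term), N, p_fisher, p_ease, fdr, minus_log10_p and genes,
#'   sorted by the ranking statistic.
#' @export
enrich <- function(query, background, sets, rank_by = c("ease", "fisher")) {
  rank_by <- match.arg(rank_by)
  query <- unique(query)
  background <- unique(background)
  drop <- setdiff(query, background)
  if (length(drop)) {
    warnf("enrich: %d query genes outside the background dropped", length(drop))
    query <- intersect(query, background)
  }
  if (!length(query)) {
    warnf("enrich: empty query")
    return(data.frame(term = character(), term_name = character(),
                      k = integer(), n_query = integer(), K = integer(),
                      N = integer(), p_fisher = double(), p_ease = double(),
                      fdr = double(), minus_log10_p = double(),
                      genes = character(), stringsAsFactors = FALSE))
  }
  N <- length(background)
  n <- length(query)
  desc <- attr(sets, "description") %||% names(sets)
  rows <- lapply(seq_along(sets), function(i) {
    members <- intersect(sets[[i]], background)
    hit <- intersect(query, members)
    if (!length(hit)) return(NULL)
    k <- length(hit); K <- length(members)
    data.frame(term = names(sets)[i], term_name = desc[i], k = k, n_query = n,
               K = K, N = N, p_fisher = fisher_tail(k, K, n, N),
               p_ease = ease_score(k, K, n, N),
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(), term_name = character(),
                      k = integer(), n_query = integer(), K = integer(),
                      N = integer(), p_fisher = double(), p_ease = double(),
                      fdr = double(), minus_log10_p = double(),
                      genes = character(), stringsAsFactors = FALSE))
  }
  p_rank <- if (rank_by == "ease") out$p_ease else out$p_fisher
  out$fdr <- stats::p.adjust(p_rank, "BH")
  out$minus_log10_p <- -log10(p_rank)
  out <- out[order(p_rank, -out$k), ]
  rownames(out) <- NULL
  out[c("term", "term_name", "k", "n_query", "K", "N", "p_fisher", "p_ease",
        "fdr", "minus_log10_p", "genes")]
}
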