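#' Build a ranked gene list from a differential-expression table
#'
#' Orders genes by the chosen metric, descending; ties break by gene name so
#' the enrichment score (which depends on order) is deterministic. Rows with
#' an undefined metric are dropped with a warning.
#'
#' @param de a [differential_expression()] table, or any data.frame with a
#'   `gene` column and the metric column.
#' @param metric column to rank by (default `"log2FC"`).
#' @return named numeric vector, metric values named by gene, descending;
#'   attribute `n_dropped` records removed NaN/NA rows.
#' @export
rank_genes <- function(de, metric = "log2FC") {
  stop_if_not(nrow(de) > 0, "empty differential-expression table")
  stop_if_not(metric %in% names(de), "no '%s' column", metric)
  r <- setNames(de[[metric]], de$gene)
  bad <- !is.finite(r)
  if (any(bad)) {
    warning(sprintf("dropping %d gene(s) with undefined ranking metric",
                    sum(bad)))
    r <- r[!bad]
  }
  stop_if_not(!anyDuplicated(names(r)), "duplicate genes in ranking")
  r <- r[order(-r, names(r))]
  if (length(unique(r)) == 1)
    attr(r, "degenerate") <- TRUE
  attr(r, "n_dropped") <- sum(bad)
  r
}

## core weighted Kolmogorov-Smirnov statistic, evaluated only at hit
## positions and the points immediately before them (the extrema candidates)
es_stat <- function(hits_sorted, absr, N, p = 1) {
  k <- length(hits_sorted)
  w <- absr[hits_sorted]^p
  sw <- sum(w)
  if (sw == 0) w <- rep(1 / k, k) else w <- w / sw
  phit <- cumsum(w)
  miss_at <- (hits_sorted - seq_len(k)) / (N - k)
  dev_at <- phit - miss_at                       # just after each hit
  dev_before <- c(0, phit[-k]) -
    (hits_sorted - 1 - (seq_len(k) - 1)) / (N - k)  # just before each hit
  lo <- min(dev_before)
  hi <- max(dev_at)
  if (hi >= -lo) hi else lo
}

#' Weighted running-sum enrichment score
#'
#' The preranked GSEA statistic: walking down the ranked list, hits increment
#' the running sum by `|r|^p` (normalized over the set's hits) and misses
#' decrement it by `1/(N - N_hit)`; the enrichment score is the maximum signed
#' deviation. The leading edge ("core enrichment") contains the hit genes at
#' or before the extremum (at or after it, for a negative score).
#'
#' @param ranked a [rank_genes()] vector (named metric values, descending).
#' @param gene_set character vector; must intersect the ranked universe and
#'   must not equal it.
#' @param p weight exponent (default 1, the classic weighted statistic; 0
#'   gives the unweighted Kolmogorov-Smirnov form).
#' @return list with `ES`, `running_sum` (length N), `leading_edge`,
#'   `hits` (positions).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  N <- length(ranked)
  hits <- which(names(ranked) %in% gene_set)
  stop_if_not(length(hits) >= 1, "gene set does not intersect the universe")
  stop_if_not(length(hits) < N, "gene set equals the whole universe")
  k <- length(hits)
  w <- abs(ranked[hits])^p
  sw <- sum(w)
  if (sw == 0) w <- rep(1 / k, k) else w <- w / sw
  inc <- rep(-1 / (N - k), N)
  inc[hits] <- w
  running <- cumsum(inc)
  es <- es_stat(hits, abs(ranked), N, p)
  if (es >= 0) {
    peak <- which.max(running)
    le <- hits[hits <= peak]
  } else {
    trough <- which.min(c(0, running)[seq_len(N)])  # position before which running is lowest
    le <- hits[hits >= trough]
  }
  list(ES = unname(es), running_sum = unname(running),
       leading_edge = names(ranked)[le], hits = hits)
}

#' Preranked gene-set enrichment analysis
#'
#' Computes the weighted enrichment score for every set whose intersection
#' with the universe has between `min_size` and `max_size` genes (10-800 by
#' default), builds a gene-label permutation null per set (`n_perm` draws of
#' the same number of positions), normalizes ES by the mean |null ES| of
#' matching sign, computes one-sided permutation p-values with the +1
#' correction, adjusts across retained sets by Benjamini-Hochberg, and flags
#' a result "relevant" only when p_adj < `alpha` and the leading edge holds
#' more than one gene.
#'
#' @param ranked a [rank_genes()] vector.
#' @param sets named list of gene sets (e.g. [read_gmt()]).
#' @param min_size,max_size set-size window after intersection (10 and 800).
#' @param n_perm permutations per set (default 1000; < 100 warns).
#' @param p weight exponent passed to [enrichment_score()].
#' @param alpha relevance threshold on p_adj (default 0.05).
#' @param seed integer seed for the permutation draws.
#' @return data.frame per retained set: `set`, `size_used`, `ES`, `NES`, `p`,
#'   `p_adj`, `n_leading_edge`, `leading_edge` (semicolon-joined), `relevant`,
#'   `no_same_sign_null` flag.
#' @export
gsea_preranked <- function(ranked, sets, min_size = 10, max_size = 800,
                           n_perm = 1000, p = 1, alpha = 0.05, seed = 1L) {
  if (n_perm < 100) warning("fewer than 100 permutations: p-values are coarse")
  N <- length(ranked)
  universe <- names(ranked)
  absr <- abs(ranked)
  kept <- Filter(function(s) {
    k <- length(intersect(s, universe))
    k >= min_size && k <= max_size && k < N
  }, sets)
  stop_if_not(length(kept) > 0, "no gene set passes the size filter")
  obs <- lapply(kept, function(s) enrichment_score(ranked, s, p))
  sizes <- vapply(obs, function(o) length(o$hits), integer(1))
  with_seed(seed, {
    rows <- lapply(seq_along(kept), function(i) {
      o <- obs[[i]]; k <- sizes[i]
      null_es <- vapply(seq_len(n_perm), function(j)
        es_stat(sort(sample.int(N, k)), absr, N, p), numeric(1))
      same <- null_es[sign(null_es) == sign(o$ES)]
      if (length(same) == 0) {
        nes <- NA_real_
        pval <- 1 / (1 + n_perm)
        flag <- TRUE
      } else {
        nes <- o$ES / mean(abs(same))
        pval <- (1 + sum(abs(same) >= abs(o$ES))) / (1 + length(same))
        flag <- FALSE
      }
      data.frame(set = names(kept)[i], size_used = k, ES = o$ES, NES = nes,
                 p = pval, n_leading_edge = length(o$leading_edge),
                 leading_edge = paste(o$leading_edge, collapse = ";"),
                 no_same_sign_null = flag, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_adj <- p.adjust(out$p, method = "BH")
    out$relevant <- out$p_adj < alpha & out$n_leading_edge > 1
    rownames(out) <- NULL
    out[order(out$p, out$set),
        c("set", "size_used", "ES", "NES", "p", "p_adj",
          "n_leading_edge", "leading_edge", "relevant", "no_same_sign_null")]
  })
}
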