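#' Posterior gene inclusion probabilities
#'
#' Monte-Carlo frequency estimates: the inclusion probability of gene i
#' is the fraction of retained draws in which gamma_i = 1.  Genes are
#' ranked by probability descending, ties broken by original gene index.
#'
#' @param chain a [run_chain] result with at least one retained draw.
#' @return A data.frame of class `gsg_ranking` with columns `rank`,
#'   `gene_id`, `gene_index`, `inclusion_probability`, ordered by rank.
#' @export
inclusion_probabilities <- function(chain) {
  M <- nrow(chain$gamma)
  if (is.null(M) || M < 1L) stop("chain has no retained draws")
  prob <- colMeans(chain$gamma)
  p <- length(prob)
  ord <- order(-prob, seq_len(p))
  out <- data.frame(rank = seq_len(p),
                    gene_id = chain$gene_ids[ord],
                    gene_index = ord,
                    inclusion_probability = prob[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("gsg_ranking", "data.frame")
  out
}

#' Select the top genes of a ranking
#'
#' @param ranking a [inclusion_probabilities] result.
#' @param p_star number of genes to keep (`0 <= p_star <= p`); the
#'   analyses in this package typically use values such as 6, 10 or 14.
#' @return Integer vector of `p_star` original gene indices in rank
#'   order.
#' @export
select_top <- function(ranking, p_star) {
  if (p_star > nrow(ranking)) stop("p_star exceeds the number of genes")
  ranking$gene_index[seq_len(p_star)]
}
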