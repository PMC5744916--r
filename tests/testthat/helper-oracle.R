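# Independent brute-force oracle for rule mining: plain loops over all
# antecedent subsets, counts by row filtering, productivity p-values via
# stats::fisher.test (one-sided), then filter/sort/top-k.  Deliberately
# shares no code with mine_rules().

oracle_mine <- function(M, target, max_size = 3, k = 50, alpha = 0.05,
                        measure = "leverage") {
  n <- nrow(M)
  attr_of <- function(x) sub("=.*$", "", x)
  eligible <- setdiff(colnames(M)[attr_of(colnames(M)) != attr_of(target)],
                      target)
  c_vec <- M[, target]
  q <- sum(c_vec)
  if (q == 0 || q == n) return(NULL)
  cands <- list()
  for (s in seq_len(min(max_size, length(eligible)))) {
    combos <- utils::combn(eligible, s, simplify = FALSE)
    cands <- c(cands, combos)
  }
  fisher_p <- function(items, cov_a, sup_a) {
    # max one-sided Fisher p over immediate generalisations
    ps <- vapply(seq_along(items), function(d) {
      g <- items[-d]
      in_g <- if (length(g)) rowSums(M[, g, drop = FALSE]) == length(g)
              else rep(TRUE, n)
      N <- sum(in_g); K <- sum(in_g & c_vec)
      tab <- matrix(c(sup_a, cov_a - sup_a, K - sup_a,
                      N - K - cov_a + sup_a), 2, 2)
      stats::fisher.test(tab, alternative = "greater")$p.value
    }, 0)
    max(ps)
  }
  rows <- lapply(cands, function(items) {
    in_a <- rowSums(M[, items, drop = FALSE]) == length(items)
    cov_a <- sum(in_a)
    sup_a <- sum(in_a & c_vec)
    strength <- if (cov_a > 0) sup_a / cov_a else 0
    data.frame(antecedent = paste(items, collapse = ";"),
               size = length(items), cover_count = cov_a,
               support_count = sup_a,
               strength = strength, lift = strength / (q / n),
               leverage = sup_a / n - (cov_a / n) * (q / n),
               coverage = cov_a / n, support = sup_a / n,
               p_productive = fisher_p(items, cov_a, sup_a),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  space <- sum(choose(length(eligible), seq_len(min(max_size,
                                                    length(eligible)))))
  out$significant <- out$p_productive <= alpha / space
  out <- out[out$significant, , drop = FALSE]
  out <- out[order(-out[[measure]], out$size, out$antecedent), ,
             drop = FALSE]
  utils::head(out, k)
}

# random item matrix with distinct attributes; target column "y" is a
# noisy function of the first column so some rules exist
rand_item_matrix <- function(nrow, ncol, seed, assoc = TRUE) {
  set.seed(seed)
  M <- matrix(stats::runif(nrow * ncol) < stats::runif(ncol, 0.15, 0.6),
              nrow = nrow,
              dimnames = list(NULL, paste0("a", seq_len(ncol))))
  p_y <- if (assoc) ifelse(M[, 1], 0.7, 0.25) else 0.4
  cbind(M, y = stats::runif(nrow) < p_y)
}
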