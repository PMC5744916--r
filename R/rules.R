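# Statistically sound association rule mining.
#
# k-optimal discovery of rules (antecedent of up to three items ->
# target item) ranked by an interestingness measure, with a productivity
# filter (one-sided hypergeometric test of the rule's strength against
# every immediate generalisation) and Bonferroni familywise-error control
# over the exact size of the searched candidate space.

#' Encode a cohort as a binary item matrix
#'
#' One row per analysis unit, one logical column per (attribute, value)
#' item.  Multi-valued attributes (triggers, interventions, outcome
#' flags) contribute one column per label; intervention and outcome
#' columns are named by the bare label (each flag is its own attribute),
#' categorical attributes as `attribute=value`.
#'
#' @param cohort a [met_cohort()].
#' @param level `"first_call_patient"` (one row per patient, attributes
#'   of the first call; the development-analysis unit) or `"call"` (one
#'   row per call).
#' @return logical matrix with row names (patient or call ids).
#' @export
encode_records <- function(cohort,
                           level = c("first_call_patient", "call")) {
  level <- match.arg(level)
  if (nrow(cohort$calls) == 0) stop("empty cohort")
  if (level == "first_call_patient") {
    ca <- first_calls(cohort)
    ids <- ca$patient_id
  } else {
    ca <- cohort$calls
    ids <- ca$call_id
  }
  ep <- cohort$episodes[match(ca$patient_id, cohort$episodes$patient_id),
                        , drop = FALSE]
  n <- nrow(ca)
  cols <- list()
  for (lab in met_vocab$triggers) {
    cols[[paste0("trigger=", lab)]] <- cell_has(ca$triggers, lab)
  }
  for (lab in met_vocab$locations) {
    cols[[paste0("location=", lab)]] <- ca$location == lab
  }
  for (lab in met_vocab$clinical_units) {
    cols[[paste0("clinical_unit=", lab)]] <- ep$clinical_unit == lab
  }
  for (lab in met_vocab$diagnosis_groups) {
    cols[[paste0("diagnosis_group=", lab)]] <- ep$diagnosis_group == lab
  }
  for (lab in met_vocab$interventions) {
    cols[[lab]] <- cell_has(ca$interventions, lab)
  }
  for (lab in met_vocab$outcome_flags) {
    cols[[lab]] <- cell_has(ca$outcome_flags, lab)
  }
  M <- do.call(cbind, cols)
  rownames(M) <- ids
  M
}

# attribute part of an item column name ("location=x" -> "location";
# bare flag columns are their own attribute)
item_attribute <- function(colnames) {
  sub("=.*$", "", colnames)
}

#' Mining configuration
#'
#' @param target_attribute column name of the consequent item in the
#'   encoded matrix (e.g. `"iv_fluid"`).
#' @param max_antecedent_size maximum antecedent size (1-3).
#' @param k number of rules retained.
#' @param ranking_measure one of `leverage` (default), `lift`,
#'   `strength`, `support`, `coverage`.
#' @param alpha familywise error level for the Bonferroni-corrected
#'   productivity filter.
#' @param exhaustive disable the admissible leverage-bound pruning and
#'   enumerate every candidate unconditionally (the two paths return
#'   identical results; the flag exists for verification).
#' @return list of class `mining_config`.
#' @export
mining_config <- function(target_attribute, max_antecedent_size = 3L,
                          k = 50L,
                          ranking_measure = c("leverage", "lift",
                                              "strength", "support",
                                              "coverage"),
                          alpha = 0.05, exhaustive = FALSE) {
  ranking_measure <- match.arg(ranking_measure)
  stopifnot(k >= 1, alpha > 0, alpha < 1,
            max_antecedent_size >= 1, max_antecedent_size <= 3)
  structure(list(target_attribute = target_attribute,
                 max_antecedent_size = as.integer(max_antecedent_size),
                 k = as.integer(k), ranking_measure = ranking_measure,
                 alpha = alpha, exhaustive = exhaustive),
            class = "mining_config")
}

#' Leverage of a rule from its counts
#'
#' Excess joint frequency over the expectation under independence:
#' `support/n - (cover/n) * (consequent/n)`.
#'
#' @param rule list (or one-row data frame) with `n`, `cover_count`,
#'   `support_count`, `consequent_count`.
#' @return numeric leverage in \[-0.25, 0.25\].
#' @export
leverage_of <- function(rule) {
  if (rule$n == 0) stop("leverage undefined for n = 0")
  rule$support_count / rule$n -
    (rule$cover_count / rule$n) * (rule$consequent_count / rule$n)
}

# Upper bound on the leverage of any specialisation of an antecedent:
# a superset's support is at most support(A & c) and its cover at least
# its support, so leverage <= (support(A & c)/n) * (1 - q/n).
leverage_upper_bound <- function(support_count, n, consequent_count) {
  (support_count / n) * (1 - consequent_count / n)
}

#' Exact size of the mined candidate space
#'
#' Number of (antecedent, consequent) pairs the search enumerates for a
#' matrix with `n_items` eligible antecedent columns: all antecedent
#' subsets of size 1..`max_size`.  Used as the Bonferroni denominator.
#'
#' @param n_items eligible antecedent columns.
#' @param max_size maximum antecedent size.
#' @return integer count.
#' @export
rule_search_space <- function(n_items, max_size = 3L) {
  sum(choose(n_items, seq_len(min(max_size, n_items))))
}

#' Productivity test of a rule against its immediate generalisations
#'
#' For each generalisation G (the antecedent minus one item; for a
#' single-item antecedent, the empty antecedent whose strength is the
#' consequent base rate), a one-sided hypergeometric (Fisher) test that
#' the rule's strength exceeds G's, evaluated within G's cover.  A rule
#' is productive when every such test is small; the maximum p across
#' generalisations is returned.
#'
#' @param rule list with `antecedent` (character vector of column names)
#'   and `consequent` (column name).
#' @param matrix binary item matrix (as from [encode_records()]).
#' @return the maximum one-sided p-value.
#' @export
productivity_test <- function(rule, matrix) {
  ant <- rule$antecedent
  stopifnot(length(ant) >= 1, all(ant %in% colnames(matrix)),
            rule$consequent %in% colnames(matrix))
  c_vec <- matrix[, rule$consequent]
  cover_of <- function(items) {
    if (length(items) == 0) rep(TRUE, nrow(matrix))
    else Reduce(`&`, lapply(items, function(j) matrix[, j]))
  }
  cov_a <- cover_of(ant)
  k_obs <- sum(cov_a & c_vec)
  n_a <- sum(cov_a)
  ps <- vapply(seq_along(ant), function(drop) {
    g <- cover_of(ant[-drop])
    N <- sum(g); K <- sum(g & c_vec)
    stats::phyper(k_obs - 1, K, N - K, n_a, lower.tail = FALSE)
  }, 0)
  max(ps)
}

#' Bonferroni significance filter
#'
#' Marks a rule significant iff its productivity p-value is at most
#' `alpha / search_space_size`, controlling the familywise error over
#' every candidate the search enumerated.
#'
#' @param rules a `met_rules` data frame (from [mine_rules()]) or any
#'   data frame with a `p_productive` column.
#' @param search_space_size number of candidate (antecedent, consequent)
#'   pairs in the searched space.
#' @param alpha familywise level.
#' @return `rules` with its `significant` column set.
#' @export
bonferroni_filter <- function(rules, search_space_size, alpha = 0.05) {
  if (search_space_size == 0) stop("search_space_size is 0")
  rules$significant <- rules$p_productive <= alpha / search_space_size
  rules
}

#' Mine statistically sound association rules
#'
#' Enumerates every antecedent of up to `max_antecedent_size` items
#' (excluding items sharing the consequent's attribute), computes
#' support/cover/strength/lift/leverage, applies the Bonferroni-corrected
#' productivity filter, and returns the `k` significant rules with the
#' highest ranking measure.  The search is admissible: pruning (a
#' leverage upper bound on specialisations) discards only candidates
#' that provably cannot enter the result, so the output is identical to
#' exhaustive enumeration.
#'
#' @param matrix logical item matrix from [encode_records()].
#' @param config a [mining_config()].
#' @return data frame of class `met_rules`, ordered by the ranking
#'   measure (ties: smaller antecedent first, then lexically).
#' @export
mine_rules <- function(matrix, config) {
  stopifnot(inherits(config, "mining_config"), nrow(matrix) >= 1)
  if (!config$target_attribute %in% colnames(matrix)) {
    stop("target column not in matrix: ", config$target_attribute)
  }
  n <- nrow(matrix)
  c_vec <- as.numeric(matrix[, config$target_attribute])
  q <- sum(c_vec)
  empty <- function() {
    out <- data.frame(antecedent = character(), consequent = character(),
                      n = integer(), cover_count = integer(),
                      support_count = integer(),
                      consequent_count = integer(), strength = numeric(),
                      lift = numeric(), leverage = numeric(),
                      p_productive = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
    structure(out, class = c("met_rules", "data.frame"),
              search_space = 0L, target = config$target_attribute)
  }
  if (q == 0 || q == n) {
    warning("degenerate target (constant column); no rules mined")
    return(empty())
  }
  tgt_attr <- item_attribute(config$target_attribute)
  eligible <- setdiff(colnames(matrix)[item_attribute(colnames(matrix)) !=
                                         tgt_attr],
                      config$target_attribute)
  m <- length(eligible)
  if (m == 0) return(empty())
  M <- matrix[, eligible, drop = FALSE] + 0   # numeric 0/1 copy
  space <- rule_search_space(m, config$max_antecedent_size)
  thresh <- config$alpha / space

  cov1 <- colSums(M)
  sup1 <- as.vector(crossprod(M, c_vec))

  cand <- list(data.frame(i1 = seq_len(m), i2 = NA_integer_,
                          i3 = NA_integer_, cover = cov1, sup = sup1))
  cov2m <- sup2m <- NULL
  if (config$max_antecedent_size >= 2 && m >= 2) {
    cov2m <- crossprod(M)
    sup2m <- crossprod(M * c_vec, M)
    pr <- which(upper.tri(cov2m), arr.ind = TRUE)
    cand[[2]] <- data.frame(i1 = pr[, 1], i2 = pr[, 2], i3 = NA_integer_,
                            cover = cov2m[pr], sup = sup2m[pr])
  }
  if (config$max_antecedent_size >= 3 && m >= 3) {
    # admissible pruning: after significance-filtering the size-1/2
    # candidates, any base item whose leverage upper bound falls below
    # the provisional k-th best significant leverage cannot contribute a
    # top-k triple
    skip <- rep(FALSE, m)
    if (!config$exhaustive && config$ranking_measure == "leverage") {
      c12 <- do.call(rbind, cand)
      lev12 <- c12$sup / n - (c12$cover / n) * (q / n)
      p12 <- .productivity_p(c12, n, q, cov1, sup1, cov2m, sup2m)
      sig_lev <- sort(lev12[p12 <= thresh], decreasing = TRUE)
      if (length(sig_lev) >= config$k) {
        kth <- sig_lev[config$k]
        skip <- leverage_upper_bound(sup1, n, q) < kth
      }
    }
    trip <- vector("list", m)
    for (i in seq_len(m)) {
      if (skip[i] || i > m - 2) next
      rows <- M[, i] == 1
      later <- (i + 1):m
      if (!any(rows)) {
        nc <- length(later)
        prr <- which(upper.tri(diag(nc)), arr.ind = TRUE)
        if (nrow(prr)) {
          trip[[i]] <- data.frame(i1 = i, i2 = later[prr[, 1]],
                                  i3 = later[prr[, 2]], cover = 0,
                                  sup = 0)
        }
        next
      }
      Ms <- M[rows, later, drop = FALSE]
      cs <- c_vec[rows]
      cov3 <- crossprod(Ms)
      sup3 <- crossprod(Ms * cs, Ms)
      prr <- which(upper.tri(cov3), arr.ind = TRUE)
      if (nrow(prr)) {
        trip[[i]] <- data.frame(i1 = i, i2 = later[prr[, 1]],
                                i3 = later[prr[, 2]], cover = cov3[prr],
                                sup = sup3[prr])
      }
    }
    cand[[3]] <- do.call(rbind, trip)
  }
  cd <- do.call(rbind, cand)

  cd$strength <- ifelse(cd$cover > 0, cd$sup / cd$cover, 0)
  cd$lift <- cd$strength / (q / n)
  cd$leverage <- cd$sup / n - (cd$cover / n) * (q / n)
  cd$coverage <- cd$cover / n
  cd$support <- cd$sup / n
  cd$p_productive <- .productivity_p(cd, n, q, cov1, sup1, cov2m, sup2m)
  cd$significant <- cd$p_productive <= thresh

  keep <- cd[cd$significant, , drop = FALSE]
  size <- 1L + !is.na(keep$i2) + !is.na(keep$i3)
  ant_label <- function(r) {
    vapply(seq_along(r$i1), function(j) {
      paste(eligible[stats::na.omit(c(r$i1[j], r$i2[j], r$i3[j]))],
            collapse = ";")
    }, "")
  }
  labels <- ant_label(keep)
  meas <- keep[[config$ranking_measure]]
  ord <- order(-meas, size, labels)
  keep <- keep[ord, , drop = FALSE]
  labels <- labels[ord]
  keep <- utils::head(keep, config$k)
  labels <- utils::head(labels, config$k)
  out <- data.frame(
    antecedent = labels,
    consequent = rep(config$target_attribute, length(labels)),
    n = rep(n, length(labels)),
    cover_count = as.integer(keep$cover),
    support_count = as.integer(keep$sup),
    consequent_count = rep(as.integer(q), length(labels)),
    strength = keep$strength,
    lift = keep$lift,
    leverage = keep$leverage,
    p_productive = keep$p_productive,
    significant = keep$significant,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("met_rules", "data.frame"),
            search_space = space, target = config$target_attribute)
}

# Vectorised productivity p-values for a candidate count table.  For
# each candidate the generalisation counts are looked up in the size-1
# vectors / size-2 matrices; the returned value is the max over the
# immediate generalisations of the one-sided hypergeometric tail.
.productivity_p <- function(cd, n, q, cov1, sup1, cov2m, sup2m) {
  pmax_tail <- function(p, covG, supG, covA, supA) {
    pmax(p, stats::phyper(supA - 1, supG, covG - supG, covA,
                          lower.tail = FALSE))
  }
  p <- rep(0, nrow(cd))
  s1 <- is.na(cd$i2)
  if (any(s1)) {
    p[s1] <- stats::phyper(cd$sup[s1] - 1, q, n - q, cd$cover[s1],
                           lower.tail = FALSE)
  }
  s2 <- !is.na(cd$i2) & is.na(cd$i3)
  if (any(s2)) {
    pp <- stats::phyper(cd$sup[s2] - 1, sup1[cd$i1[s2]],
                        cov1[cd$i1[s2]] - sup1[cd$i1[s2]], cd$cover[s2],
                        lower.tail = FALSE)
    pp <- pmax_tail(pp, cov1[cd$i2[s2]], sup1[cd$i2[s2]], cd$cover[s2],
                    cd$sup[s2])
    p[s2] <- pp
  }
  s3 <- !is.na(cd$i3)
  if (any(s3)) {
    g12 <- cbind(cd$i1[s3], cd$i2[s3])
    g13 <- cbind(cd$i1[s3], cd$i3[s3])
    g23 <- cbind(cd$i2[s3], cd$i3[s3])
    pp <- stats::phyper(cd$sup[s3] - 1, sup2m[g12],
                        cov2m[g12] - sup2m[g12], cd$cover[s3],
                        lower.tail = FALSE)
    pp <- pmax_tail(pp, cov2m[g13], sup2m[g13], cd$cover[s3], cd$sup[s3])
    pp <- pmax_tail(pp, cov2m[g23], sup2m[g23], cd$cover[s3], cd$sup[s3])
    p[s3] <- pp
  }
  p
}

#' @export
print.met_rules <- function(x, ...) {
  cat(sprintf("%d significant rule(s) -> %s (search space: %d candidates)\n",
              nrow(x), attr(x, "target") %||% "?",
              attr(x, "search_space") %||% NA_integer_))
  if (nrow(x)) {
    show <- x[, c("antecedent", "cover_count", "support_count",
                  "strength", "lift", "leverage", "p_productive")]
    print.data.frame(show, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
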