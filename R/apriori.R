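#' @title Level-wise Apriori frequent-itemset mining
#' @description
#' Exact Apriori implementation over the transaction incidence matrix.
#' Level k candidates are generated by joining frequent (k-1)-itemsets
#' that share a (k-2)-prefix; within each prefix group the joint counts
#' of all tail pairs are obtained in one cross-product of the
#' prefix-projected incidence matrix, so counting stays exact while the
#' level expansion is fully vectorized (support is anti-monotone, so any
#' candidate with an infrequent subset simply fails its count). Support
#' is stored as an absolute transaction count, matching the integer
#' supports the study reports and filters on. All output is in canonical
#' lexicographic item order, so results are deterministic.
#' @name apriori
NULL

# Pack the columns of a k x m index matrix into character keys for exact
# vectorized lookup across levels.
idx_keys <- function(idx) {
  if (ncol(idx) == 0) return(character(0))
  do.call(paste, c(lapply(seq_len(nrow(idx)), function(r) idx[r, ]),
                   list(sep = ",")))
}

# One level expansion: from the k x m matrix of frequent k-itemset column
# indices (columns in lexicographic order) to the frequent (k+1)-sets.
expand_level <- function(idx, mat01, min_support_count) {
  k <- nrow(idx)
  m <- ncol(idx)
  prefix_key <- if (k == 1) rep("", m) else idx_keys(idx[-k, , drop = FALSE])
  new_idx <- list()
  new_cnt <- list()
  grp_starts <- which(!duplicated(prefix_key))
  grp_ends <- c(grp_starts[-1] - 1L, m)
  for (g in seq_along(grp_starts)) {
    cols <- grp_starts[g]:grp_ends[g]
    if (length(cols) < 2) next
    tails <- idx[k, cols]                     # ascending within the group
    prefix <- if (k == 1) integer(0) else idx[-k, cols[1]]
    rows <- rep(TRUE, nrow(mat01))
    for (p in prefix) rows <- rows & (mat01[, p] == 1L)
    C <- crossprod(mat01[rows, tails, drop = FALSE])
    hits <- which(upper.tri(C) & C >= min_support_count, arr.ind = TRUE)
    if (!nrow(hits)) next
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    new_idx[[length(new_idx) + 1]] <-
      rbind(matrix(prefix, nrow = k - 1, ncol = nrow(hits)),
            tails[hits[, 1]], tails[hits[, 2]])
    new_cnt[[length(new_cnt) + 1]] <- C[hits]
  }
  if (!length(new_idx)) return(NULL)
  list(idx = do.call(cbind, new_idx), cnt = as.integer(unlist(new_cnt)))
}

#' Mine frequent itemsets
#'
#' @param db a `transaction_db`.
#' @param min_support_count minimum absolute support (>= 1).
#' @param max_size largest itemset size to mine (default 4 = up to three
#'   antecedent items plus a single-outcome consequent).
#' @return data.frame of class `frequent_itemsets`: `itemset` (labels
#'   joined by `" & "` in canonical order), `items` (list column), `size`,
#'   `support_count`; attributes `N` and `min_support_count`.
#' @export
mine_frequent_itemsets <- function(db, min_support_count, max_size = 4) {
  stopifnot(inherits(db, "transaction_db"),
            min_support_count >= 1, max_size >= 1)
  finish <- function(res, levels) {
    attr(res, "N") <- db$N
    attr(res, "min_support_count") <- min_support_count
    attr(res, "levels") <- levels
    class(res) <- c("frequent_itemsets", "data.frame")
    res
  }
  empty <- data.frame(itemset = character(0), size = integer(0),
                      support_count = integer(0))
  empty$items <- list()
  if (db$N == 0 || ncol(db$mat) == 0) return(finish(empty, list()))

  mat01 <- db$mat * 1L
  cnt1 <- colSums(mat01)
  f1 <- which(cnt1 >= min_support_count)
  if (!length(f1)) return(finish(empty, list()))

  levels <- list(list(idx = matrix(as.integer(f1), nrow = 1),
                      cnt = as.integer(cnt1[f1])))
  k <- 1
  while (k < max_size) {
    nxt <- expand_level(levels[[k]]$idx, mat01, min_support_count)
    if (is.null(nxt)) break
    levels[[k + 1]] <- nxt
    k <- k + 1
  }

  chunks <- lapply(seq_along(levels), function(k) {
    idx <- levels[[k]]$idx
    labels <- lapply(seq_len(k), function(r) db$catalog[idx[r, ]])
    data.frame(
      itemset = do.call(paste, c(labels, list(sep = ITEM_SEP))),
      size = k,
      support_count = levels[[k]]$cnt,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, chunks)
  res$items <- strsplit(res$itemset, ITEM_SEP, fixed = TRUE)
  res <- res[order(res$size, res$itemset), , drop = FALSE]
  rownames(res) <- NULL
  finish(res, levels)
}

#' Generate association rules from frequent itemsets
#'
#' Emits every rule `X -> Y` with consequent `Y` drawn from
#' `rhs_constraint`, antecedent size at most `max_lhs`, and `X union Y`
#' frequent. Metrics are exact: `confidence = count(X u Y) / count(X)`,
#' `lift = confidence * N / count(Y)` (`count(X)` and `count(Y)` are
#' frequent by anti-monotonicity, so both come from the mined table).
#'
#' @param frequent output of [mine_frequent_itemsets()].
#' @param db the `transaction_db` the itemsets were mined on.
#' @param rhs_constraint list of allowed consequent itemsets (character
#'   vectors); default single-outcome consequents `"PD"` and `"SD"`.
#' @param max_lhs maximum antecedent size (default 3).
#' @return data.frame of class `rule_set`: `lhs`, `rhs` (canonical
#'   `" & "`-joined labels), `support_count`, `support_fraction`,
#'   `confidence`, `lift`; attribute `N`.
#' @export
generate_rules <- function(frequent, db,
                           rhs_constraint = list("PD", "SD"),
                           max_lhs = 3) {
  stopifnot(inherits(frequent, "frequent_itemsets"),
            inherits(db, "transaction_db"), max_lhs >= 1)
  rhs_constraint <- lapply(rhs_constraint, sort_items)
  for (y in rhs_constraint) {
    absent <- setdiff(y, db$catalog)
    if (length(absent)) stop("consequent item absent from transactions: ",
                             paste(absent, collapse = ", "))
  }
  N <- attr(frequent, "N")
  levels <- attr(frequent, "levels")
  empty <- {
    e <- data.frame(lhs = character(0), rhs = character(0),
                    support_count = integer(0), support_fraction = numeric(0),
                    confidence = numeric(0), lift = numeric(0))
    attr(e, "N") <- N
    class(e) <- c("rule_set", "data.frame")
    e
  }
  if (!length(levels)) return(empty)
  level_keys <- lapply(levels, function(l) idx_keys(l$idx))

  count_of <- function(item_idx) {
    k <- length(item_idx)
    if (k > length(levels)) return(NA_integer_)
    hit <- match(paste(item_idx, collapse = ","), level_keys[[k]])
    if (is.na(hit)) NA_integer_ else levels[[k]]$cnt[hit]
  }

  chunks <- list()
  for (y in rhs_constraint) {
    y_idx <- sort(match(y, db$catalog))
    cy <- count_of(y_idx)
    if (is.na(cy)) next  # target itself below the support floor: no rules
    for (k in seq_along(levels)) {
      if (k <= length(y_idx) || k > max_lhs + length(y_idx)) next
      idx <- levels[[k]]$idx
      has_y <- rep(TRUE, ncol(idx))
      for (yi in y_idx) has_y <- has_y & colSums(idx == yi) > 0
      sel <- which(has_y)
      if (!length(sel)) next
      sub <- idx[, sel, drop = FALSE]
      keep <- !matrix(sub %in% y_idx, nrow = k)
      x_mat <- matrix(sub[keep], nrow = k - length(y_idx))
      cx <- levels[[nrow(x_mat)]]$cnt[match(idx_keys(x_mat),
                                            level_keys[[nrow(x_mat)]])]
      cf <- levels[[k]]$cnt[sel]
      lhs_labels <- lapply(seq_len(nrow(x_mat)),
                           function(r) db$catalog[x_mat[r, ]])
      chunks[[length(chunks) + 1]] <- data.frame(
        lhs = do.call(paste, c(lhs_labels, list(sep = ITEM_SEP))),
        rhs = paste(y, collapse = ITEM_SEP),
        support_count = cf,
        support_fraction = cf / N,
        confidence = cf / cx,
        lift = (cf / cx) * N / cy,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(chunks)) return(empty)
  res <- do.call(rbind, chunks)
  res <- res[order(res$rhs, res$lhs), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "N") <- N
  class(res) <- c("rule_set", "data.frame")
  res
}

#' Mine association rules in one step
#'
#' Convenience wrapper: frequent itemsets at `min_support_count` up to
#' `max_lhs + max(consequent size)`, then [generate_rules()].
#'
#' @inheritParams generate_rules
#' @inheritParams mine_frequent_itemsets
#' @return `rule_set` data.frame.
#' @export
mine_rules <- function(db, min_support_count,
                       rhs_constraint = list("PD", "SD"), max_lhs = 3) {
  max_size <- max_lhs + max(vapply(rhs_constraint, length, integer(1)))
  freq <- mine_frequent_itemsets(db, min_support_count, max_size)
  generate_rules(freq, db, rhs_constraint, max_lhs)
}

#' @export
print.rule_set <- function(x, n = 10, sep = " ∩ ", ...) {
  cat(sprintf("Association rules: %d rule(s), N = %s\n", nrow(x),
              attr(x, "N") %||% "?"))
  shown <- utils::head(x, n)
  for (i in seq_len(nrow(shown))) {
    cat(sprintf("  %s => %s  [support %d, conf %.2f, lift %.2f]\n",
                gsub(ITEM_SEP, sep, shown$lhs[i], fixed = TRUE),
                shown$rhs[i], shown$support_count[i],
                shown$confidence[i], shown$lift[i]))
  }
  if (nrow(x) > n) cat(sprintf("  ... %d more\n", nrow(x) - n))
  invisible(x)
}
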