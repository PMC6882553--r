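#' Assemble the child-round by item response matrix
#'
#' Harmonises long-format records into a binary matrix with one row per
#' child-round and one column per item. Raw scores are recoded through each
#' item's recode rule. Because each cohort-round administers only a subset
#' of instruments, the matrix has planned (structural) missingness; cells
#' never administered are \code{NA}.
#'
#' @param records Long data frame with columns \code{child_id, cohort,
#'   round, age_months, item_code, raw_score}.
#' @param bank An \code{\link{item_bank}}.
#' @param rules Named list of \code{\link{recode_rule}} objects covering
#'   every rule id referenced by the bank.
#' @return An object of class \code{dscale_matrix}: a list with
#'   \code{scores} (integer matrix, rows child-rounds, columns items),
#'   \code{meta} (data frame \code{child_id, cohort, round, age_months} per
#'   row) and \code{log} (build counts).
#' @export
assemble_matrix <- function(records, bank, rules = default_recode_rules()) {
  stopifnot(inherits(bank, "dscale_bank"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  unknown <- setdiff(unique(records$item_code), bank$item_code)
  if (length(unknown) > 0)
    stop("item(s) not in bank: ", paste(head(unknown, 5), collapse = ", "))
  if (any(records$age_months < 0, na.rm = TRUE))
    stop("age_months must be >= 0")
  key <- paste(records$child_id, records$round, records$item_code, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE]
    stop(sprintf("duplicate (child, round, item) records, e.g. (%s, %s, %s)",
                 d$child_id[1], d$round[1], d$item_code[1]))
  }
  rule_of <- setNames(bank$recode_rule, bank$item_code)
  score <- rep(NA_integer_, nrow(records))
  for (rid in unique(rule_of[records$item_code])) {
    if (!rid %in% names(rules))
      stop(sprintf("recode rule '%s' not supplied", rid))
    sel <- rule_of[records$item_code] == rid
    score[sel] <- recode(records$raw_score[sel], rules[[rid]],
                         records$item_code[sel])
  }
  if (any(!score %in% c(0L, 1L, NA_integer_)))
    stop("non-binary score after recoding")

  row_key <- paste(records$child_id, records$round, sep = "\r")
  rows <- !duplicated(row_key)
  meta <- data.frame(child_id = records$child_id[rows],
                     cohort = records$cohort[rows],
                     round = records$round[rows],
                     age_months = NA_real_,
                     stringsAsFactors = FALSE)
  rk <- row_key[rows]
  meta$age_months <- as.numeric(tapply(records$age_months, row_key, mean)[rk])
  items <- intersect(bank$item_code, unique(records$item_code))
  m <- matrix(NA_integer_, nrow(meta), length(items),
              dimnames = list(rk, items))
  m[cbind(match(row_key, rk), match(records$item_code, items))] <- score
  rownames(m) <- NULL
  log <- list(n_child_rounds = nrow(m), n_items = ncol(m),
              n_observed = sum(!is.na(m)),
              n_children = length(unique(meta$child_id)))
  structure(list(scores = m, meta = meta, log = log),
            class = "dscale_matrix")
}

#' @export
print.dscale_matrix <- function(x, ...) {
  cat(sprintf(
    "<dscale_matrix> %d child-rounds x %d items, %d observed cells (%.1f%% filled), %d children\n",
    x$log$n_child_rounds, x$log$n_items, x$log$n_observed,
    100 * x$log$n_observed / (nrow(x$scores) * max(1, ncol(x$scores))),
    x$log$n_children))
  invisible(x)
}

#' Remove items with a sparse response category
#'
#' An item is removed when the least populated response category (pass or
#' fail) has fewer than \code{min_count} observations, pooled over all
#' cohorts. Items with too few passes or too few fails carry almost no
#' information about their difficulty and destabilise pairwise estimation.
#'
#' @param rm A \code{\link{assemble_matrix}} result.
#' @param min_count Minimum observations required in each response
#'   category (default 10). An item with exactly \code{min_count} in each
#'   category is retained.
#' @return List with \code{matrix} (filtered \code{dscale_matrix}) and
#'   \code{removed} (data frame \code{item, n_pass, n_fail}).
#' @export
filter_sparse_items <- function(rm, min_count = 10) {
  stopifnot(inherits(rm, "dscale_matrix"))
  m <- rm$scores
  n_pass <- colSums(m == 1L, na.rm = TRUE)
  n_fail <- colSums(m == 0L, na.rm = TRUE)
  drop <- pmin(n_pass, n_fail) < min_count
  removed <- data.frame(item = colnames(m)[drop],
                        n_pass = unname(n_pass[drop]),
                        n_fail = unname(n_fail[drop]),
                        stringsAsFactors = FALSE)
  rm$scores <- m[, !drop, drop = FALSE]
  rm$log$n_items <- ncol(rm$scores)
  rm$log$n_observed <- sum(!is.na(rm$scores))
  rm$log$sparse_removed <- nrow(removed)
  list(matrix = rm, removed = removed)
}

#' Partition items into linked components
#'
#' Two items are linked when (i) at least one child-round observed both, or
#' (ii) they share an active equate group. Difficulties are identified on a
#' common scale only within a linked component; estimation should proceed
#' on the largest component.
#'
#' @param rm A \code{dscale_matrix} (typically after
#'   \code{\link{filter_sparse_items}}).
#' @param bank An \code{\link{item_bank}}.
#' @param active_groups Equate-group ids to treat as active links; default
#'   the bank's candidate-active groups.
#' @return List of character vectors (item codes), largest component
#'   first. A disconnected bank raises a warning.
#' @export
connectivity_check <- function(rm, bank,
                               active_groups = unique(
                                 bank$equate_group[bank$active &
                                                     !is.na(bank$equate_group)])) {
  stopifnot(inherits(rm, "dscale_matrix"))
  items <- colnames(rm$scores)
  obs <- !is.na(rm$scores)
  co <- crossprod(obs) > 0   # items co-observed by >= 1 child-round
  g <- igraph::graph_from_adjacency_matrix(co, mode = "undirected",
                                           diag = FALSE)
  eg <- bank$equate_group[match(items, bank$item_code)]
  for (grp in intersect(active_groups, eg)) {
    members <- items[!is.na(eg) & eg == grp]
    if (length(members) >= 2)
      g <- igraph::add_edges(g, as.vector(utils::combn(members, 2)))
  }
  comp <- igraph::components(g)
  out <- split(items, comp$membership)
  out <- out[order(-vapply(out, length, 1L))]
  names(out) <- NULL
  if (length(out) > 1)
    warning(sprintf(
      "item graph is disconnected: %d components (largest %d of %d items)",
      length(out), length(out[[1]]), length(items)))
  out
}

#' Subset a response matrix to a set of items
#'
#' @param rm A \code{dscale_matrix}.
#' @param items Item codes to keep.
#' @param drop_empty_rows Drop child-rounds left with no observed item.
#' @return A \code{dscale_matrix}.
#' @export
subset_items <- function(rm, items, drop_empty_rows = FALSE) {
  stopifnot(inherits(rm, "dscale_matrix"))
  keep <- intersect(colnames(rm$scores), items)
  rm$scores <- rm$scores[, keep, drop = FALSE]
  if (drop_empty_rows) {
    nz <- rowSums(!is.na(rm$scores)) > 0
    rm$scores <- rm$scores[nz, , drop = FALSE]
    rm$meta <- rm$meta[nz, , drop = FALSE]
  }
  rm$log$n_child_rounds <- nrow(rm$scores)
  rm$log$n_items <- ncol(rm$scores)
  rm$log$n_observed <- sum(!is.na(rm$scores))
  rm$log$n_children <- length(unique(rm$meta$child_id))
  rm
}
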