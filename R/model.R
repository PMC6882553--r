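#' Configuration for model building
#'
#' @param min_count Sparse-item filter threshold (minimum observations in
#'   the least populated response category), default 10.
#' @param tol,max_iter,eps Passed to \code{\link{estimate_difficulties}}.
#' @param activation_range Maximum spread (logits) of a candidate equate
#'   group's member difficulties, estimated freely per member and cohort on
#'   the common ability scale, for the group to be activated. Default 0.5.
#' @param activation_fit_max Maximum infit/outfit a member may reach under
#'   the constraint for the group to stay active. Default 1.2.
#' @param activation_min_n Minimum responses per member-cohort cell used in
#'   the spread screen. Default 30.
#' @param active_groups Optional explicit activation list overriding the
#'   screen (the choice of active groups is partly judgment-based, so it
#'   must be overridable).
#' @param max_retention_iter Maximum estimate/fit/retain alternations.
#' @param dif Run the cross-group differential item functioning screen.
#' @param dif_min_n,dif_threshold,dif_alpha Passed to \code{\link{dif_flag}}.
#' @param dif_policy \code{"exclude"} drops flagged items from the model;
#'   \code{"keep"} only records the verdicts.
#' @param anchors An \code{\link{anchor_spec}}, or \code{NULL} to skip
#'   anchoring (difficulties stay in logits).
#' @return A list of class \code{dscale_config}.
#' @export
model_config <- function(min_count = 10, tol = 1e-8, max_iter = 2000,
                         eps = 0.05, activation_range = 0.5,
                         activation_fit_max = 1.2, activation_min_n = 30,
                         active_groups = NULL, max_retention_iter = 5,
                         dif = TRUE, dif_min_n = 30, dif_threshold = 0.5,
                         dif_alpha = 0.05,
                         dif_policy = c("exclude", "keep"),
                         anchors = anchor_spec()) {
  structure(list(min_count = min_count, tol = tol, max_iter = max_iter,
                 eps = eps, activation_range = activation_range,
                 activation_fit_max = activation_fit_max,
                 activation_min_n = activation_min_n,
                 active_groups = active_groups,
                 max_retention_iter = max_retention_iter, dif = dif,
                 dif_min_n = dif_min_n, dif_threshold = dif_threshold,
                 dif_alpha = dif_alpha,
                 dif_policy = match.arg(dif_policy), anchors = anchors),
            class = "dscale_config")
}

# Flat-prior EAP abilities on the logit scale, used inside fit statistics.
abilities_logit <- function(rm, delta_logit) {
  m <- rm$scores[, names(delta_logit)[names(delta_logit) %in%
                                        colnames(rm$scores)], drop = FALSE]
  mid <- mean(range(delta_logit))
  span <- diff(range(delta_logit)) / 2 + 8
  eap_batch(m, delta_logit, a = 1, prior_mean = mid, prior_sd = 50,
            span = span)$d_score
}

# Spread of a candidate group's member difficulties when that group alone
# is released from its equality constraint (all other active groups stay
# constrained so the instruments remain linked). NA when releasing the
# group disconnects the comparison graph (the group is then needed for
# linking and cannot be screened).
group_spread <- function(counts, g, active, clusters_for, members,
                         config) {
  cl <- clusters_for(setdiff(active, g))
  d <- tryCatch(suppressWarnings(
    estimate_difficulties(counts, cl, tol = config$tol,
                          max_iter = config$max_iter, eps = config$eps)),
    error = function(e) NULL)
  if (is.null(d)) return(NA_real_)
  mem <- intersect(members, names(d))
  if (length(mem) < 2) return(NA_real_)
  diff(range(d[mem]))
}

#' Build an equate-constrained Rasch model from harmonised data
#'
#' Multistep pipeline: (1) remove items with a sparse response category;
#' (2) restrict to the largest linked component; (3) estimate difficulties
#' with all candidate equate groups constrained, then screen candidates,
#' deactivating groups whose members' freely estimated difficulties spread
#' more than \code{activation_range} logits across instruments and cohorts
#' or whose constrained fit exceeds \code{activation_fit_max}; (4)
#' alternate estimation, EAP abilities, infit/outfit and the retention rule
#' (active-equate members always retained; independent items only with
#' infit and outfit < 1) until the retained set is stable; (5) flag
#' differential item functioning across groups (default: cohorts) for
#' independent items and apply the exclusion policy; (6) final estimate and
#' anchoring to D-score units.
#'
#' @param rm A \code{dscale_matrix} from \code{\link{assemble_matrix}}.
#' @param bank An \code{\link{item_bank}}.
#' @param config A \code{\link{model_config}}.
#' @param grouping Group labels per child-round for the DIF screen
#'   (default the cohort column; pass country labels when cohorts share a
#'   country).
#' @return An object of class \code{dscale_model}: named difficulties in
#'   logits and D units, the anchoring transform, constraint clusters,
#'   active groups, fit statistics, DIF verdicts and a step-by-step build
#'   log.
#' @export
build_model <- function(rm, bank, config = model_config(),
                        grouping = NULL) {
  stopifnot(inherits(rm, "dscale_matrix"), inherits(bank, "dscale_bank"))
  if (is.null(grouping)) grouping <- rm$meta$cohort
  log <- list(input = rm$log)

  fs <- filter_sparse_items(rm, config$min_count)
  rm <- fs$matrix
  removed <- if (nrow(fs$removed) > 0)
    data.frame(item = fs$removed$item, stage = "sparse",
               reason = sprintf("min response category below %d",
                                config$min_count),
               stringsAsFactors = FALSE)
  else data.frame(item = character(), stage = character(),
                  reason = character(), stringsAsFactors = FALSE)
  log$after_sparse_filter <- rm$log

  candidates <- unique(bank$equate_group[bank$active &
                                           !is.na(bank$equate_group)])
  grp_of <- setNames(bank$equate_group, bank$item_code)
  live_members <- function(g)
    intersect(bank$item_code[!is.na(grp_of[bank$item_code]) &
                               grp_of[bank$item_code] == g],
              colnames(rm$scores))
  candidates <- Filter(function(g) {
    mem <- live_members(g)
    length(mem) >= 2 &&
      length(unique(bank$instrument[match(mem, bank$item_code)])) >= 2
  }, candidates)

  comps <- withCallingHandlers(
    connectivity_check(rm, bank, active_groups = candidates),
    warning = function(w) invokeRestart("muffleWarning"))
  if (length(comps) > 1) {
    off <- unlist(comps[-1])
    removed <- rbind(removed, data.frame(
      item = off, stage = "connectivity",
      reason = "outside the largest linked component",
      stringsAsFactors = FALSE))
    row_keep <- rowSums(!is.na(rm$scores[, intersect(colnames(rm$scores),
                                                     comps[[1]]),
                                         drop = FALSE])) > 0
    rm <- subset_items(rm, comps[[1]], drop_empty_rows = TRUE)
    grouping <- grouping[row_keep]
    warning(sprintf(
      "item graph disconnected; proceeding on the largest component (%d of %d items)",
      length(comps[[1]]), length(comps[[1]]) + length(off)))
  }
  log$components <- length(comps)

  clusters_for <- function(active) {
    mem <- bank$item_code[!is.na(grp_of[bank$item_code]) &
                            grp_of[bank$item_code] %in% active]
    setNames(paste0("eq:", grp_of[mem]), mem)
  }
  fit_once <- function(rm, active) {
    counts <- pairwise_counts(rm)
    delta <- estimate_difficulties(counts, clusters_for(active),
                                   tol = config$tol,
                                   max_iter = config$max_iter,
                                   eps = config$eps)
    theta <- abilities_logit(rm, delta)
    list(counts = counts, delta = delta, theta = theta)
  }

  # anchor-bearing groups define the metric and are never deactivated
  anchor_items <- if (!is.null(config$anchors))
    c(config$anchors$item_lo, config$anchors$item_hi) else character()
  anchor_groups <- unique(na.omit(grp_of[anchor_items]))

  active <- candidates
  st <- fit_once(rm, active)

  if (is.null(config$active_groups)) {
    fit <- infit_outfit(rm, st$delta, st$theta)
    spread <- vapply(active, function(g)
      group_spread(st$counts, g, active, clusters_for, live_members(g),
                   config), numeric(1))
    keep <- vapply(seq_along(active), function(i) {
      g <- active[i]
      if (g %in% anchor_groups) return(TRUE)
      f <- fit[fit$item %in% live_members(g), ]
      ok_fit <- all(na.omit(c(f$infit, f$outfit)) <
                      config$activation_fit_max)
      (is.na(spread[i]) || spread[i] < config$activation_range) && ok_fit
    }, logical(1))
    log$activation_spread <- setNames(spread, active)
    if (!all(keep)) {
      # deactivate worst-spreading groups first, but only while the
      # comparison graph stays connected without them
      drop_order <- active[!keep][order(-spread[!keep], na.last = TRUE)]
      for (g in drop_order) {
        trial <- setdiff(active, g)
        ok <- tryCatch({
          suppressWarnings(estimate_difficulties(
            st$counts, clusters_for(trial), tol = 1e-2, max_iter = 5,
            eps = config$eps))
          TRUE
        }, error = function(e) FALSE)
        if (ok) active <- trial
      }
      st <- fit_once(rm, active)
    }
  } else {
    active <- union(intersect(config$active_groups, candidates),
                    intersect(anchor_groups, candidates))
    st <- fit_once(rm, active)
  }
  log$active_groups <- active

  for (iter in seq_len(config$max_retention_iter)) {
    fit <- infit_outfit(rm, st$delta, st$theta)
    ret <- retention_pass(fit, bank, active)
    # the anchor milestones define the metric and are kept regardless
    keep_anchor <- intersect(anchor_items, ret$removed$item)
    if (length(keep_anchor) > 0) {
      ret$retained <- c(ret$retained, keep_anchor)
      ret$removed <- ret$removed[!ret$removed$item %in% keep_anchor, ,
                                 drop = FALSE]
    }
    if (nrow(ret$removed) == 0) break
    if (length(ret$retained) < 2) {
      warning("retention rule would leave fewer than 2 items; keeping the current set")
      break
    }
    removed <- rbind(removed, data.frame(
      item = ret$removed$item, stage = sprintf("retention_%d", iter),
      reason = ret$removed$reason, stringsAsFactors = FALSE))
    rm <- subset_items(rm, ret$retained)
    st <- fit_once(rm, active)
  }
  log$after_retention <- rm$log

  dif <- NULL
  if (isTRUE(config$dif) && length(unique(grouping)) >= 2) {
    indep <- setdiff(colnames(rm$scores),
                     names(clusters_for(active)))
    if (length(indep) > 0) {
      dif <- dif_flag(rm, st$delta, grouping, items = indep,
                      min_n = config$dif_min_n,
                      threshold = config$dif_threshold,
                      alpha = config$dif_alpha)
      flagged <- setdiff(dif$item[dif$verdict == "flagged"], anchor_items)
      if (config$dif_policy == "exclude" && length(flagged) > 0) {
        removed <- rbind(removed, data.frame(
          item = flagged, stage = "dif",
          reason = "differential performance across groups",
          stringsAsFactors = FALSE))
        rm <- subset_items(rm, setdiff(colnames(rm$scores), flagged))
        st <- fit_once(rm, active)
      }
    }
  }

  fit <- infit_outfit(rm, st$delta, st$theta)
  anchor <- NULL
  delta_d <- NULL
  if (!is.null(config$anchors)) {
    tr <- anchor_transform(st$delta, config$anchors)
    anchor <- list(item_lo = config$anchors$item_lo,
                   item_hi = config$anchors$item_hi,
                   value_lo = config$anchors$value_lo,
                   value_hi = config$anchors$value_hi,
                   a = tr$a, b = tr$b)
    delta_d <- tr$delta_d
  }
  log$final <- rm$log

  structure(list(
    delta_logit = st$delta, delta_d = delta_d, anchor = anchor,
    clusters = attr(st$delta, "clusters"), active_groups = active,
    fit = fit, dif = dif, retained = colnames(rm$scores),
    removed = removed, config = config, log = log),
    class = "dscale_model")
}

#' @export
print.dscale_model <- function(x, ...) {
  cat(sprintf("<dscale_model> %d items retained, %d active equate groups\n",
              length(x$retained), length(x$active_groups)))
  if (!is.null(x$anchor))
    cat(sprintf("  anchored: %.4f D/logit slope, offset %.4f (anchors at %g and %g D)\n",
                x$anchor$a, x$anchor$b, x$anchor$value_lo,
                x$anchor$value_hi))
  cat(sprintf("  removed: %d items (%s)\n", nrow(x$removed),
              paste(sprintf("%s: %d", names(table(x$removed$stage)),
                            table(x$removed$stage)), collapse = ", ")))
  invisible(x)
}

#' Write a fitted model to JSON
#'
#' The JSON carries one record per retained item (code, constraint
#' cluster, difficulty in logits and D units, fit statistics, DIF verdict)
#' plus the anchoring transform and configuration; numbers are written at
#' full precision so a rerun with the same inputs is byte-identical.
#'
#' @param model A \code{dscale_model}.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  items <- data.frame(
    code = names(model$delta_logit),
    cluster = unname(model$clusters[names(model$delta_logit)]),
    delta_logit = unname(model$delta_logit),
    stringsAsFactors = FALSE)
  if (!is.null(model$delta_d))
    items$delta_d <- unname(model$delta_d[items$code])
  items$infit <- model$fit$infit[match(items$code, model$fit$item)]
  items$outfit <- model$fit$outfit[match(items$code, model$fit$item)]
  if (!is.null(model$dif)) {
    items$dif <- model$dif$verdict[match(items$code, model$dif$item)]
    items$dif[is.na(items$dif)] <- "not tested"
  }
  cfg <- unclass(model$config)
  cfg$anchors <- NULL
  jsonlite::write_json(
    list(items = items, anchor = model$anchor,
         active_groups = model$active_groups,
         removed = model$removed, config = cfg),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a model JSON written by \code{\link{write_model}}
#'
#' Restores the components needed for scoring (difficulties, clusters,
#' anchor transform).
#'
#' @param path JSON path.
#' @return A \code{dscale_model} (without build log or matrices).
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  delta_logit <- setNames(j$items$delta_logit, j$items$code)
  delta_d <- if (!is.null(j$items$delta_d))
    setNames(j$items$delta_d, j$items$code) else NULL
  structure(list(
    delta_logit = delta_logit, delta_d = delta_d, anchor = j$anchor,
    clusters = setNames(j$items$cluster, j$items$code),
    active_groups = j$active_groups,
    fit = data.frame(item = j$items$code, infit = j$items$infit,
                     outfit = j$items$outfit, stringsAsFactors = FALSE),
    dif = NULL, retained = j$items$code, removed = j$removed,
    config = j$config, log = NULL), class = "dscale_model")
}
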