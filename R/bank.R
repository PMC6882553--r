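#' Developmental domains recognised by the item bank
#'
#' Five domains are modelled; personal-social development is excluded
#' because its expression and interpretation vary too much across cultures
#' to support cross-instrument linking.
#' @export
DSCALE_DOMAINS <- c("fine motor", "gross motor", "receptive language",
                    "expressive language", "cognition")

#' Anchor difficulties admissible for bank items (D-score units)
#'
#' The scale metric is defined by two widely measured motor milestones fixed
#' at 20 and 40 D-score units; any \code{anchor_value} in a bank must be one
#' of these constants.
#' @export
DSCALE_ANCHOR_VALUES <- c(20, 40)

#' Define a recoding rule mapping instrument-native raw scores to 0/1
#'
#' Instruments score items in different native schemes (e.g. 0/1/2 with two
#' passing levels, or 0/5/10 for not yet / sometimes / succeeds). A recode
#' rule is a total mapping from the instrument's raw score set to binary
#' fail/pass, with an optional alternate mapping for designated exception
#' items (e.g. items mapped to a harder skill in another instrument, where a
#' partial pass must count as a fail).
#'
#' @param id Rule identifier.
#' @param mapping Named numeric vector; names are raw scores (as character),
#'   values are 0 or 1.
#' @param exception_items Character vector of item codes that use
#'   \code{exception_mapping} instead. Empty by default.
#' @param exception_mapping Alternate named mapping for exception items.
#'   Required when \code{exception_items} is non-empty.
#' @return An object of class \code{recode_rule}.
#' @export
recode_rule <- function(id, mapping, exception_items = character(),
                        exception_mapping = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  if (is.null(names(mapping)) || any(!mapping %in% c(0, 1)))
    stop("`mapping` must be a named vector with values 0 or 1")
  if (length(exception_items) > 0 && is.null(exception_mapping))
    stop("exception items declared without an exception mapping")
  if (!is.null(exception_mapping) &&
      (is.null(names(exception_mapping)) ||
       any(!exception_mapping %in% c(0, 1))))
    stop("`exception_mapping` must be a named vector with values 0 or 1")
  structure(list(id = id, mapping = mapping,
                 exception_items = as.character(exception_items),
                 exception_mapping = exception_mapping),
            class = "recode_rule")
}

#' Built-in recode rules
#'
#' \describe{
#'   \item{binary}{identity on 0/1 (already harmonised data).}
#'   \item{pass2}{0/1/2 scheme with two passing levels: 2 is recoded to 1.
#'     Exception items (partial pass mapped to a harder cross-instrument
#'     skill) recode 1 to 0; the exception set is configured per bank and is
#'     empty by default.}
#'   \item{notyet10}{0/5/10 (not yet / sometimes / succeeds) scheme: both 5
#'     and 10 are recoded to 1.}
#' }
#'
#' @param pass2_exceptions Item codes using the alternate mapping under the
#'   \code{pass2} rule.
#' @return Named list of \code{\link{recode_rule}} objects.
#' @export
default_recode_rules <- function(pass2_exceptions = character()) {
  list(
    binary = recode_rule("binary", c(`0` = 0, `1` = 1)),
    pass2 = recode_rule(
      "pass2", c(`0` = 0, `1` = 1, `2` = 1),
      exception_items = pass2_exceptions,
      exception_mapping = c(`0` = 0, `1` = 0, `2` = 1)),
    notyet10 = recode_rule("notyet10", c(`0` = 0, `5` = 1, `10` = 1))
  )
}

#' Recode raw instrument scores to binary fail/pass
#'
#' Applies a \code{\link{recode_rule}} elementwise. Recoding is idempotent
#' for already-binary scores under any rule whose mapping fixes 0 and 1.
#'
#' @param raw_score Numeric vector of instrument-native raw scores.
#' @param rule A \code{\link{recode_rule}}.
#' @param item_code Character vector (recycled) of item codes; items listed
#'   in the rule's exception set use the alternate mapping.
#' @return Integer vector of 0/1 scores; \code{NA} raw scores stay missing.
#' @export
recode <- function(raw_score, rule, item_code = NA_character_) {
  stopifnot(inherits(rule, "recode_rule"))
  item_code <- rep_len(as.character(item_code), length(raw_score))
  out <- rep(NA_integer_, length(raw_score))
  obs <- !is.na(raw_score)
  key <- as.character(raw_score[obs])
  use_exc <- item_code[obs] %in% rule$exception_items
  map <- rule$mapping
  bad <- !use_exc & !(key %in% names(map))
  if (!is.null(rule$exception_mapping))
    bad <- bad | (use_exc & !(key %in% names(rule$exception_mapping)))
  else bad <- bad | use_exc
  if (any(bad))
    stop(sprintf("raw score(s) %s not in the domain of recode rule '%s'",
                 paste(unique(key[bad]), collapse = ", "), rule$id))
  val <- numeric(sum(obs))
  val[!use_exc] <- map[key[!use_exc]]
  if (any(use_exc)) val[use_exc] <- rule$exception_mapping[key[use_exc]]
  out[obs] <- as.integer(val)
  out
}

#' Construct and validate an item bank
#'
#' The item bank is the master table of items across instruments: one row
#' per item, with its developmental domain, optional equate-group
#' membership (same-skill items from different instruments), an activity
#' flag marking the group as a candidate for difficulty-equality
#' constraints, an optional anchor value, and the recode rule that maps the
#' instrument's raw scores to 0/1.
#'
#' @param items Data frame with columns \code{item_code},
#'   \code{instrument}, \code{domain}, and optionally \code{equate_group}
#'   (NA = independent item), \code{active} (logical, candidate equate
#'   groups), \code{anchor_value} (NA or one of
#'   \code{\link{DSCALE_ANCHOR_VALUES}}), \code{recode_rule} (default
#'   \code{"binary"}).
#' @return A validated data frame of class \code{dscale_bank}.
#' @export
item_bank <- function(items) {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  req <- c("item_code", "instrument", "domain")
  if (!all(req %in% names(items)))
    stop("item bank needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(items$item_code))
    stop("duplicated item codes: ",
         paste(unique(items$item_code[duplicated(items$item_code)]),
               collapse = ", "))
  if (!all(items$domain %in% DSCALE_DOMAINS))
    stop("unknown domain(s): ",
         paste(setdiff(unique(items$domain), DSCALE_DOMAINS), collapse = ", "))
  if (is.null(items$equate_group)) items$equate_group <- NA_character_
  if (is.null(items$active)) items$active <- !is.na(items$equate_group)
  if (is.null(items$anchor_value)) items$anchor_value <- NA_real_
  if (is.null(items$recode_rule)) items$recode_rule <- "binary"
  av <- items$anchor_value
  if (!all(is.na(av) | av %in% DSCALE_ANCHOR_VALUES))
    stop("anchor_value must be one of ",
         paste(DSCALE_ANCHOR_VALUES, collapse = "/"))
  eg <- split(items, items$equate_group)
  for (g in eg) {
    if (nrow(g) < 2)
      stop(sprintf("equate group '%s' has fewer than 2 members",
                   g$equate_group[1]))
    if (length(unique(g$instrument)) < 2)
      stop(sprintf("equate group '%s' does not span 2 instruments",
                   g$equate_group[1]))
  }
  class(items) <- c("dscale_bank", "data.frame")
  items
}

#' Read an item bank from CSV
#'
#' Expects columns \code{item_code, instrument, domain, equate_group,
#' active, anchor_value, recode_rule}; empty strings are treated as missing.
#'
#' @param path CSV path (UTF-8, header required).
#' @return A \code{\link{item_bank}} object.
#' @export
read_item_bank <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!is.null(d$active)) d$active <- as.logical(d$active)
  item_bank(d)
}

#' Read long-format responses from CSV
#'
#' Expects columns \code{child_id, cohort, round, age_months, item_code,
#' raw_score}.
#'
#' @param path CSV path (UTF-8, header required).
#' @return Data frame of long records.
#' @export
read_responses <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("child_id", "cohort", "round", "age_months", "item_code",
           "raw_score")
  if (!all(req %in% names(d)))
    stop("responses need columns: ", paste(req, collapse = ", "))
  d
}

#' @export
print.dscale_bank <- function(x, ...) {
  cat(sprintf(
    "<dscale_bank> %d items, %d instruments, %d equate groups (%d candidate-active)\n",
    nrow(x), length(unique(x$instrument)),
    length(unique(x$equate_group[!is.na(x$equate_group)])),
    length(unique(x$equate_group[!is.na(x$equate_group) & x$active]))))
  invisible(x)
}
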