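#' Clinical fall-risk labeling rules
#'
#' Convert clinical test scores into binary fall-risk labels using the
#' published screening cut-offs:
#' \describe{
#'   \item{TUG}{time strictly over 12.47 s indicates mobility problems;}
#'   \item{SFBBS}{a score strictly below 23 (of 28) indicates balance
#'     problems — subjects at 23-28 are labeled healthy;}
#'   \item{SPMSQ}{three or more incorrect answers (of 10) indicate abnormal
#'     cognition.}
#' }
#' All three return the label `"fall_risk"` or `"healthy"` per element.
#' Labels are monotone in the score: worsening a score can never flip a
#' `fall_risk` label back to `healthy`.
#'
#' @param tug_seconds Positive TUG completion time(s) in seconds.
#' @param sfbbs_points Integer SFBBS score(s) in 0..28 (7 items, 0-4 each).
#' @param spmsq_errors Integer SPMSQ error count(s) in 0..10.
#' @return Character vector of `"healthy"` / `"fall_risk"`.
#' @examples
#' label_tug(c(12.47, 13))   # "healthy" "fall_risk"
#' label_bbs(c(22, 23, 28))  # "fall_risk" "healthy" "healthy"
#' label_spmsq(c(2, 3))      # "healthy" "fall_risk"
#' @name labeling
NULL

.lab <- function(risk) ifelse(risk, "fall_risk", "healthy")

#' @rdname labeling
#' @export
label_tug <- function(tug_seconds) {
  stopifnot(is.numeric(tug_seconds))
  if (any(!is.finite(tug_seconds)) || any(tug_seconds <= 0)) {
    stop("invalid TUG time: must be positive and finite")
  }
  .lab(tug_seconds > 12.47)
}

#' @rdname labeling
#' @export
label_bbs <- function(sfbbs_points) {
  stopifnot(is.numeric(sfbbs_points))
  if (any(!is.finite(sfbbs_points)) || any(sfbbs_points != round(sfbbs_points)) ||
      any(sfbbs_points < 0) || any(sfbbs_points > 28)) {
    stop("invalid SFBBS score: must be an integer in 0..28")
  }
  .lab(sfbbs_points < 23)
}

#' @rdname labeling
#' @export
label_spmsq <- function(spmsq_errors) {
  stopifnot(is.numeric(spmsq_errors))
  if (any(!is.finite(spmsq_errors)) || any(spmsq_errors != round(spmsq_errors)) ||
      any(spmsq_errors < 0) || any(spmsq_errors > 10)) {
    stop("invalid SPMSQ error count: must be an integer in 0..10")
  }
  .lab(spmsq_errors >= 3)
}

#' Combine two single-test labels into a multifactor label
#'
#' A subject is at fall risk under a two-test combination if and only if
#' *both* single tests flag risk (intersection rule). This makes every
#' combination count at most the minimum of its constituents' counts. The
#' rule is isolated here so a union variant is a one-argument change.
#'
#' @param label_a,label_b Character vectors of `"healthy"` / `"fall_risk"`.
#' @param rule `"and"` (default, intersection) or `"or"` (union).
#' @return Character vector of combined labels.
#' @export
label_combined <- function(label_a, label_b, rule = c("and", "or")) {
  rule <- match.arg(rule)
  ok <- c("healthy", "fall_risk")
  stopifnot(all(label_a %in% ok), all(label_b %in% ok),
            length(label_a) == length(label_b))
  a <- label_a == "fall_risk"
  b <- label_b == "fall_risk"
  .lab(if (rule == "and") a & b else a | b)
}

#' Label table for a cohort of clinical scores
#'
#' Applies the single-test rules and all pairwise combinations to a score
#' table, producing one 0/1 column per labeling condition, in canonical
#' order: `BBS`, `TUG`, `TUG + BBS`, `SPMSQ`, `TUG + SPMSQ`, `BBS + SPMSQ`
#' (columns for absent scores are omitted). 1 codes fall risk.
#'
#' @param scores Data frame with `subject_id` and any of `tug_seconds`,
#'   `sfbbs_points`, `spmsq_errors`.
#' @param rule Combination rule passed to [label_combined()].
#' @return Data frame with `subject_id` and one 0/1 integer column per
#'   condition.
#' @export
label_cohort <- function(scores, rule = "and") {
  stopifnot(is.data.frame(scores), "subject_id" %in% names(scores))
  singles <- list()
  if ("sfbbs_points" %in% names(scores))
    singles[["BBS"]] <- label_bbs(scores$sfbbs_points)
  if ("tug_seconds" %in% names(scores))
    singles[["TUG"]] <- label_tug(scores$tug_seconds)
  if ("spmsq_errors" %in% names(scores))
    singles[["SPMSQ"]] <- label_spmsq(scores$spmsq_errors)
  if (length(singles) == 0L) {
    stop("scores contains none of tug_seconds, sfbbs_points, spmsq_errors")
  }
  combos <- list(c("TUG", "BBS"), c("TUG", "SPMSQ"), c("BBS", "SPMSQ"))
  out <- data.frame(subject_id = scores$subject_id, stringsAsFactors = FALSE)
  ordering <- c("BBS", "TUG", "TUG + BBS", "SPMSQ", "TUG + SPMSQ", "BBS + SPMSQ")
  cols <- singles
  for (cb in combos) {
    if (all(cb %in% names(singles))) {
      cols[[paste(cb, collapse = " + ")]] <-
        label_combined(singles[[cb[1L]]], singles[[cb[2L]]], rule = rule)
    }
  }
  for (nm in intersect(ordering, names(cols))) {
    out[[nm]] <- as.integer(cols[[nm]] == "fall_risk")
  }
  out
}
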