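# Aggregation of VAS / body-map discomfort reports: segment retention,
# per-condition summaries and condition ranking.

check_reports <- function(reports) {
  need <- c("pid", "condition", "segment", "vas")
  miss <- setdiff(need, names(reports))
  if (length(miss)) stop("discomfort reports missing columns: ", paste(miss, collapse = ", "))
  if (!"reported" %in% names(reports)) reports$reported <- TRUE
  reports
}

#' Segments reported by at least two participants
#'
#' A segment is retained when at least `min_participants` *distinct*
#' participants reported it at any point during the whole experiment
#' (repeated reports by one participant count once).
#'
#' @param reports long-format discomfort table with columns `pid`,
#'   `condition`, `segment`, `vas` and optionally `reported`.
#' @param min_participants distinct-participant threshold (default 2).
#' @return Character vector of retained segment labels.
#' @export
filter_segments <- function(reports, min_participants = 2) {
  reports <- check_reports(reports)
  reports <- reports[reports$reported, , drop = FALSE]
  if (!nrow(reports)) return(character())
  counts <- tapply(reports$pid, reports$segment, function(p) length(unique(p)))
  sort(names(counts)[counts >= min_participants])
}

#' Per segment-condition discomfort summary
#'
#' Mean and standard error of VAS over reporting participants only, with
#' repetition-level duplicates averaged per participant first.  `se_vas` is
#' 0 when a single participant reports (documented convention).
#'
#' @inheritParams filter_segments
#' @param retained segments to keep, from [filter_segments()].
#' @return Data frame `segment`, `condition`, `n_reports`, `mean_vas`,
#'   `se_vas`.
#' @export
summarize_discomfort <- function(reports, retained = filter_segments(reports)) {
  reports <- check_reports(reports)
  reports <- reports[reports$reported & reports$segment %in% retained, , drop = FALSE]
  if (!nrow(reports)) {
    return(data.frame(segment = character(), condition = character(),
                      n_reports = integer(), mean_vas = numeric(),
                      se_vas = numeric(), stringsAsFactors = FALSE))
  }
  # one score per participant-condition-segment
  agg <- stats::aggregate(vas ~ pid + condition + segment, reports, mean)
  out <- do.call(rbind, lapply(split(agg, agg[c("segment", "condition")], drop = TRUE),
    function(d) {
      n <- nrow(d)
      data.frame(segment = d$segment[1L], condition = d$condition[1L],
                 n_reports = n, mean_vas = mean(d$vas),
                 se_vas = if (n > 1) stats::sd(d$vas) / sqrt(n) else 0,
                 stringsAsFactors = FALSE)
    }))
  out <- out[order(out$segment, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank conditions by mean discomfort for one segment
#'
#' Ascending by mean VAS; ties broken by fewer reports, then by label.
#'
#' @param summaries output of [summarize_discomfort()].
#' @param segment segment label to rank (must be present).
#' @return Character vector of condition labels, least discomfort first.
#' @export
rank_conditions_by_discomfort <- function(summaries, segment) {
  d <- summaries[summaries$segment == segment, , drop = FALSE]
  if (!nrow(d)) stop("segment not present in summaries: ", segment)
  d$condition[order(d$mean_vas, d$n_reports, d$condition)]
}
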