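# Aggregation of every upstream output into the study's result surfaces:
# per-source table, monthly volume with a November-March seasonality index,
# topic distribution table, cohort indicators and QoL tables. Every
# percentage is printed next to its own count and denominator and uses
# half-up rounding.

#' Per-source post and user counts
#'
#' Counts posts and distinct authors per source, descending by posts, with
#' a balancing totals row. Sources with fewer than `other_threshold` posts
#' are aggregated into an "Other sites" row.
#'
#' @param posts posts data frame.
#' @param other_threshold minimum posts for an own row (default 10).
#' @return data frame: source, posts, users; last row is the total.
#' @export
source_table <- function(posts, other_threshold = 10) {
  counts <- as.data.frame(table(source = posts$source),
                          stringsAsFactors = FALSE)
  names(counts)[2] <- "posts"
  counts$users <- vapply(counts$source, function(s) {
    length(unique(posts$author[posts$source == s]))
  }, integer(1))
  small <- counts$posts < other_threshold
  if (any(small)) {
    other_sources <- counts$source[small]
    other <- data.frame(
      source = "Other sites",
      posts = sum(counts$posts[small]),
      users = length(unique(posts$author[posts$source %in% other_sources])),
      stringsAsFactors = FALSE
    )
    counts <- rbind(counts[!small, , drop = FALSE], other)
  }
  counts <- counts[order(-counts$posts), , drop = FALSE]
  total <- data.frame(source = "Total", posts = nrow(posts),
                      users = length(unique(posts$author)),
                      stringsAsFactors = FALSE)
  out <- rbind(counts, total)
  rownames(out) <- NULL
  out
}

#' Monthly message volume and seasonality index
#'
#' Dense calendar-month counts over the window (months without posts appear
#' with count 0) plus the seasonality index: mean monthly volume of
#' November-March divided by mean monthly volume of April-October.
#'
#' @param posts posts data frame with ISO-8601 timestamps.
#' @param window `c("YYYY-MM", "YYYY-MM")`; defaults to the span of the
#'   data. Posts outside the window are excluded and counted.
#' @return list: `series` (month, count, cold_season), `seasonality_index`,
#'   `n_excluded`.
#' @export
monthly_volume <- function(posts, window = NULL) {
  month_of <- substr(as.character(posts$timestamp), 1, 7)
  if (is.null(window)) window <- range(month_of)
  months <- seasonal_month_table(window, amplitude = 1)
  inside <- month_of >= window[1] & month_of <= window[2]
  n_excluded <- sum(!inside)
  if (n_excluded > 0) {
    message(n_excluded, " post(s) outside the reporting window were excluded")
  }
  tab <- table(factor(month_of[inside], levels = months$label))
  series <- data.frame(
    month = months$label,
    count = as.integer(tab),
    cold_season = months$cold_season,
    stringsAsFactors = FALSE
  )
  cold <- mean(series$count[series$cold_season])
  warm <- mean(series$count[!series$cold_season])
  list(
    series = series,
    seasonality_index = if (isTRUE(warm > 0)) cold / warm else NA_real_,
    n_excluded = n_excluded
  )
}

#' Topic distribution table
#'
#' Counts and percentage shares (2 decimals, half-up) of assigned messages
#' per topic, descending; unassigned messages (`NA`) are reported
#' separately and excluded from the denominator.
#'
#' @param assignments integer vector of per-message topic ids, `NA` for
#'   unassigned messages.
#' @param labels optional topic labels (defaults to "topic k").
#' @return data frame: topic, count, pct, denominator; attribute
#'   `n_unassigned`.
#' @export
topic_table <- function(assignments, labels = NULL) {
  assigned <- assignments[!is.na(assignments)]
  denom <- length(assigned)
  tab <- table(assigned)
  ids <- as.integer(names(tab))
  if (is.null(labels)) labels <- paste("topic", ids) else labels <- labels[ids]
  out <- data.frame(
    topic = labels, count = as.integer(tab),
    pct = percentage(as.integer(tab), denom, digits = 2),
    denominator = denom, stringsAsFactors = FALSE
  )
  out <- out[order(-out$count), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unassigned") <- sum(is.na(assignments))
  out
}

#' Cohort key indicators
#'
#' Mean posts per user (2 decimals, half-up), gender shares over the
#' gender-determined users only (unknowns are reported but excluded from
#' the share denominator, and the denominator is always printed), and an
#' age histogram.
#'
#' @param posts posts data frame.
#' @param profiles user profiles from [user_profiles()].
#' @param age_breaks histogram breaks (years).
#' @return list of indicators.
#' @export
cohort_stats <- function(posts, profiles,
                         age_breaks = seq(10, 100, by = 5)) {
  n_posts <- nrow(posts)
  n_users <- length(unique(posts$author))
  determined <- profiles$gender %in% c("female", "male")
  n_det <- sum(determined)
  n_female <- sum(profiles$gender == "female")
  n_male <- sum(profiles$gender == "male")
  ages <- profiles$age[!is.na(profiles$age)]
  hist_counts <- if (length(ages) > 0) {
    h <- graphics::hist(pmin(pmax(ages, min(age_breaks)), max(age_breaks)),
                        breaks = age_breaks, plot = FALSE)
    data.frame(age_low = utils::head(age_breaks, -1),
               age_high = age_breaks[-1], count = h$counts)
  } else {
    data.frame(age_low = numeric(0), age_high = numeric(0), count = integer(0))
  }
  list(
    n_posts = n_posts,
    n_users = n_users,
    posts_per_user = round_half_up(n_posts / n_users, 2),
    n_gender_determined = n_det,
    n_female = n_female,
    n_male = n_male,
    female_share_pct = percentage(n_female, n_det, digits = 2),
    male_share_pct = percentage(n_male, n_det, digits = 2),
    mean_age = if (length(ages) > 0) round_half_up(mean(ages), 1) else NA_real_,
    age_histogram = hist_counts
  )
}

#' Self-consistency audit of an emitted table
#'
#' Recomputes every percentage of a summary table from its own printed
#' count and denominator at the stated rounding and checks exact agreement;
#' used as an output invariant on all reporting surfaces.
#'
#' @param counts,denominators,percentages parallel vectors as printed.
#' @param digits rounding of the printed percentage.
#' @return TRUE invisibly; stops with a message on any mismatch.
#' @export
audit_percentages <- function(counts, denominators, percentages, digits = 0) {
  recomputed <- percentage(counts, denominators, digits)
  bad <- which(abs(recomputed - percentages) > 1e-9)
  if (length(bad) > 0) {
    stop("percentage self-consistency failure at row(s) ",
         paste(bad, collapse = ", "), ": printed ",
         paste(percentages[bad], collapse = ", "), " recomputed ",
         paste(recomputed[bad], collapse = ", "))
  }
  invisible(TRUE)
}
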