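## Trial-style validation surfaces: censoring emulation, event-count tables,
## percent-of-observed ratios and cumulative event curves.

#' Trial-style censoring times
#'
#' The "4-y" follow-up of the validation trial had censoring times close to
#' a Uniform(3, 5.25)-year distribution; validation runs censor each twin
#' pair at a shared draw from it.
#'
#' @param n number of draws (>= 1).
#' @param min,max support in years.
#' @return numeric vector of censoring times.
#' @export
mass_censoring_times <- function(n, min = 3, max = 5.25) {
  stopifnot(n >= 1, min <= max)
  stats::runif(n, min, max)
}

#' Event-count categories reported by validation tables
#' @return character vector of category names.
#' @export
event_count_categories <- function() .count_categories

#' Tally events by category and arm
#'
#' Counts realized events for a set of simulated individual records:
#' elective operations split by detection route (screen vs incidental),
#' emergency operations, ruptures, contraindicated exits by route, AAA and
#' non-AAA deaths, and losses to recall follow-up (dropout events).
#'
#' @param records list of `aaa_record` objects (any mix of arms).
#' @param categories category names to report (default: all).
#' @return integer matrix, categories x arms.
#' @export
event_count_table <- function(records, categories = event_count_categories()) {
  unknown <- setdiff(categories, .count_categories)
  if (length(unknown))
    stop("unknown categor", if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "))
  cnt <- matrix(0L, nrow = length(.count_categories), ncol = 2,
                dimnames = list(.count_categories, c("invited", "non_invited")))
  for (r in records) {
    ar <- .arm_res_from_record(r)
    col <- if (r$arm == "invited") 1L else 2L
    cnt[, col] <- cnt[, col] + as.integer(.count_arm(ar))
  }
  cnt[categories, , drop = FALSE]
}

## Rebuild the light internal representation from a public record.
.arm_res_from_record <- function(r) {
  routes <- c("screen", "incidental")
  list(kinds = match(r$events$kind, .ev_names),
       times = r$events$time,
       end_time = r$death_time,
       alive = isTRUE(r$alive_at_censor),
       state = match(r$state, .state_names) - 1L,
       route = if (is.na(r$detection_route)) 0L else match(r$detection_route, routes),
       contra_route = if (is.na(r$contraindicated_route)) 0L
                      else match(r$contraindicated_route, routes))
}

#' Model event count as a percentage of the observed count
#'
#' Rounded to the nearest integer, halves away from zero, matching the
#' "% of observed" columns of trial-validation tables.
#'
#' @param model_count simulated count.
#' @param observed_count observed count; must be > 0 (a zero observed count
#'   gives `NA`, "not available").
#' @return integer percentage (or `NA`).
#' @export
percent_of_observed <- function(model_count, observed_count) {
  if (any(observed_count <= 0)) {
    return(ifelse(observed_count > 0,
                  percent_of_observed(model_count, pmax(observed_count, 1)),
                  NA_real_))
  }
  x <- 100 * model_count / observed_count
  sign(x) * floor(abs(x) + 0.5)
}

#' Cumulative event curve
#'
#' Non-decreasing step function of cumulative event occurrences over time;
#' its final value equals the corresponding [event_count_table()] entry for
#' count categories that are plain event tallies.
#'
#' @param records list of `aaa_record` objects.
#' @param kind event kind name (see [event_kinds()]).
#' @param arm `"invited"`, `"non_invited"`, or `NULL` for both.
#' @return data frame with `time` (sorted unique event times) and
#'   `cumulative` counts; zero rows if no events.
#' @export
cumulative_event_curve <- function(records, kind, arm = NULL) {
  if (!kind %in% .ev_names) stop("unknown event kind '", kind, "'")
  if (!is.null(arm)) {
    if (!arm %in% c("invited", "non_invited")) stop("unknown arm '", arm, "'")
    records <- Filter(function(r) r$arm == arm, records)
  }
  times <- unlist(lapply(records, function(r) r$events$time[r$events$kind == kind]))
  if (!length(times))
    return(data.frame(time = numeric(0), cumulative = integer(0)))
  tt <- sort(times)
  ut <- unique(tt)
  data.frame(time = ut, cumulative = cumsum(tabulate(match(tt, ut))))
}

#' Run a trial-emulation validation analysis
#'
#' Convenience wrapper: simulates under the validation bundle (shared
#' Uniform(3, 5.25) pair censoring, trial-era discount rates) and lays the
#' results out as the familiar validation tables -- per-arm mean life-years
#' and costs with their difference and ICER, and event counts scaled to the
#' trial group sizes (33,961 control / 33,839 invited).
#'
#' @param n_pairs simulated twin pairs.
#' @param bundle an `aaa_bundle`; defaults to the packaged
#'   `mass-validation` fixture.
#' @param draw optional realized parameters; defaults to distribution means.
#' @param seed master seed.
#' @param workers forked workers.
#' @param scale_to_groups scale event counts to these group sizes (invited,
#'   non-invited); `NULL` leaves raw counts.
#' @return list with `summary` (per-arm life-years/costs + incrementals),
#'   `events` (count table, raw and scaled), and the underlying `run`.
#' @export
run_mass_validation <- function(n_pairs, bundle = builtin_bundle("mass-validation"),
                                draw = NULL, seed = 1L, workers = 1L,
                                scale_to_groups = c(33839, 33961)) {
  if (is.null(draw)) draw <- fix_bundle_at_means(bundle)
  run <- run_main_analysis(n_pairs, draw, bundle, seed = seed,
                           workers = workers, oversample = FALSE)
  counts <- run$counts
  scaled <- if (is.null(scale_to_groups)) NULL else
    round(sweep(counts, 2, scale_to_groups / n_pairs, `*`))
  list(summary = run$ce, events = counts, events_scaled = scaled, run = run)
}
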