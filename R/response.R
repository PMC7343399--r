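# Behavioral-response classification framework.
#
# After each approach the focal animal's behavioral response is recorded as
# one of eight categories, each mapped to the threat level an approaching
# observer would have to represent to elicit it (equivalent to a predator, to
# a high-ranking social threat, a minimal threat, or no threat).  The tally of
# observed responses is read qualitatively: a group that overwhelmingly
# displaces passively treats observers like a dominant conspecific, not a
# predator and not a neutral stimulus.

.threat_table <- tibble::tribble(
  ~response_category,         ~label,                                        ~equivalent_to_predator, ~equivalent_to_social_threat, ~minimal_threat, ~no_threat,
  "alarm_bark",               "Alarm bark",                                  "yes",       "no",        "no",        "no",
  "flight_to_refuge",         "Flight direct to refuge (rocks, trees, or cliff)", "yes",  "no",        "no",        "no",
  "rapid_flight",             "Rapid flight/sprinting response",             "yes",       "yes",       "no",        "no",
  "displacement_with_geck",   "Displacement with geck/grimace",              "no",        "yes",       "no",        "no",
  "passive_displacement",     "Animal passively displaces",                  "no",        "yes",       "yes",       "no",
  "flinch_before_flight",     "Flinch/startled before flight",               "ambiguous", "ambiguous", "ambiguous", "ambiguous",
  "not_displaced",            "Animal is not displaced",                     "no",        "ambiguous", "no",        "yes",
  "not_displaced_threatens",  "Animal is not displaced and threatens observer", "no",     "no",        "no",        "yes")

#' Threat-level profiles for the behavioral response categories
#'
#' The fixed lookup mapping each of the eight response categories to the
#' threat level it is hypothesized to be equivalent to.  Entries are `"yes"`,
#' `"no"`, or `"ambiguous"` (the latter preserving explicitly uncertain
#' assignments rather than collapsing them to yes/no).
#'
#' @return A tibble with one row per category and columns
#'   `response_category`, `label`, `equivalent_to_predator`,
#'   `equivalent_to_social_threat`, `minimal_threat`, `no_threat`.
#' @export
threat_profiles <- function() .threat_table

#' Classify a behavioral response
#'
#' Looks up the threat-level profile of one response category.  Input is
#' case- and whitespace-normalized and may be either the machine label
#' (e.g. `"passive_displacement"`) or the descriptive label
#' (e.g. `"Animal passively displaces"`).
#'
#' @param category A single response label.
#' @return A one-row tibble (the category's threat profile).
#' @examples
#' classify_response("Alarm bark")
#' @export
classify_response <- function(category) {
  stopifnot(length(category) == 1)
  norm <- function(x) gsub("[^a-z]+", "_", trimws(tolower(x)))
  key <- norm(category)
  hit <- which(norm(.threat_table$response_category) == key |
                 norm(.threat_table$label) == key)
  if (length(hit) != 1) {
    stop("unknown response category ", dQuote(category), "; valid categories: ",
         paste(.threat_table$response_category, collapse = ", "))
  }
  .threat_table[hit, ]
}

# round-half-up (printed percentages use half-up, not banker's rounding)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Tally behavioral responses
#'
#' Counts trials per response category, reporting zero-count categories
#' explicitly and percentages rounded half-up to two decimals.  For an empty
#' table the counts are all zero and percentages are `NA` with the
#' `percentages_defined` attribute set to `FALSE` (never silent `NaN`s).
#'
#' @param data Trial tibble with a `response_category` column.
#' @return A tibble with `response_category`, `label`, `n`, `percent`, in the
#'   canonical category order.
#' @examples
#' cfg <- sim_config(n_individuals = 3, n_dates = 4, trials_per_observer = 2,
#'                   seed = 7)
#' tally_responses(simulate_trials(cfg))
#' @export
tally_responses <- function(data) {
  cats <- .threat_table$response_category
  bad <- setdiff(unique(data$response_category), cats)
  if (length(bad)) stop("unknown response categories: ",
                        paste(bad, collapse = ", "))
  counts <- table(factor(data$response_category, levels = cats))
  total <- sum(counts)
  out <- tibble::tibble(response_category = cats,
                        label = .threat_table$label,
                        n = as.integer(counts),
                        percent = if (total > 0)
                          round_half_up(100 * as.integer(counts) / total)
                        else NA_real_)
  attr(out, "percentages_defined") <- total > 0
  out
}
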