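# Respondent records: schema, skip-logic classification, covariate coding,
# and the descriptive-statistics layer of the survey analysis.

#' @name survey_schema
#' @title Respondent CSV schema and coding constants
#'
#' @description
#' One row per respondent, UTF-8, empty cell = missing.  Columns:
#'
#' * `id` — opaque respondent identifier.
#' * `owns_at_home_count`, `boards_count`, `leases_count` — equid-count bins,
#'   one of `"0", "1", "2-4", "5-9", "10-19", "20+"`.
#' * `current_cost` — current monthly cost of care in USD (>= 0; 0 is legal,
#'   free board exists).
#' * `lease_type`, `board_type` — `"free"`, `"partial"`, `"full"`, `"other"`
#'   or `"none"`.
#' * `disc_sport`, `disc_ranch_western`, `disc_other` — 0/1 discipline flags.
#' * `covid_stability` — `"less"`, `"same"`, `"more"` (financial stability
#'   relative to before the pandemic).
#' * `sell_or_stop_intent` — `"yes"`, `"maybe"`, `"no"` (considering selling
#'   the equid or stopping the lease).
#' * `region` — `"south"` (Census South) or `"other"`.
#' * `income_bracket` — one of [income_brackets] or missing.
#' * `age_bracket` — one of [age_brackets] or missing.
#' * `sex` — `"female"`, `"male"` or missing (recorded, never modeled).
#' * `response1`, `response2` — `"yes"`/`"no"` answers to the two bid
#'   questions.
#' * `followup_frac` — realized second-bid fraction; must lie in 0.11..0.20
#'   when `response1 = "yes"` and 0.01..0.09 when `"no"`.
NULL

#' Equid-count bins used by the survey
#' @export
count_bins <- c("0", "1", "2-4", "5-9", "10-19", "20+")

#' Annual household income brackets
#' @export
income_brackets <- c("0-25k", "25-50k", "50-75k", "75-100k", "100-150k", ">150k")

#' Respondent age brackets
#' @export
age_brackets <- c("18-24", "25-34", "35-44", "45-54", "55-64", "65-74", "75-84")

#' The 16 Census-South states
#'
#' States whose residents are coded `region = "south"`.
#' @export
south_states <- c(
  "Alabama", "Arkansas", "Delaware", "Florida", "Georgia", "Kentucky",
  "Louisiana", "Maryland", "Mississippi", "North Carolina", "Oklahoma",
  "South Carolina", "Tennessee", "Texas", "Virginia", "West Virginia"
)

#' Map a US state name to the survey region coding
#'
#' @param state character vector of state names.
#' @return `"south"` for the 16 Census-South states, `"other"` elsewhere.
#' @examples
#' state_to_region("Tennessee") # "south"
#' state_to_region("Oregon")    # "other"
#' @export
state_to_region <- function(state) {
  ifelse(tolower(trimws(state)) %in% tolower(south_states), "south", "other")
}

.check_bin <- function(x, what) {
  bad <- !is.na(x) & !(x %in% count_bins)
  if (any(bad)) stop("invalid ", what, " bin(s): ", paste(unique(x[bad]), collapse = ", "))
  x
}

#' Read a respondent CSV
#'
#' Reads and validates a file in the documented schema (see
#' [survey_schema]).  Validation errors (unknown bins, negative costs,
#' follow-up fractions inconsistent with the first response) abort.
#'
#' @param path file path.
#' @return data.frame of respondent records.
#' @export
read_respondents <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), colClasses = "character")
  required <- c(
    "id", "owns_at_home_count", "boards_count", "leases_count",
    "current_cost", "lease_type", "board_type", "disc_sport",
    "disc_ranch_western", "disc_other", "covid_stability",
    "sell_or_stop_intent", "region", "income_bracket", "age_bracket", "sex",
    "response1", "response2", "followup_frac"
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("respondent CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  num <- c("current_cost", "followup_frac", "disc_sport",
           "disc_ranch_western", "disc_other")
  df[num] <- lapply(df[num], as.numeric)
  validate_respondents(df)
}

#' Validate respondent records
#'
#' @param df data.frame in the documented schema.
#' @return `df`, invisibly validated (stops on violations).
#' @export
validate_respondents <- function(df) {
  for (col in c("owns_at_home_count", "boards_count", "leases_count")) {
    .check_bin(df[[col]], col)
  }
  if (any(df$current_cost < 0, na.rm = TRUE)) stop("current_cost must be >= 0")
  sched <- bid_schedule()
  in_support <- function(x, sup) {
    vapply(x, function(v) any(abs(v - sup) < 1e-9), logical(1))
  }
  both <- !is.na(df$response1) & !is.na(df$followup_frac)
  bad <- both & ifelse(df$response1 == "yes",
    !in_support(df$followup_frac, sched$c2y_support),
    !in_support(df$followup_frac, sched$c2n_support)
  )
  bad[is.na(bad)] <- FALSE
  if (any(bad)) {
    stop("follow-up fraction inconsistent with response1 at row(s): ",
         paste(utils::head(which(bad), 10), collapse = ", "))
  }
  df
}

#' Write a respondent CSV
#'
#' @param df data.frame of respondent records.
#' @param path output file path.
#' @export
write_respondents <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Classify respondents into owner / boarder / leaser
#'
#' Skip-logic priority classification, most limited population first:
#' any leasing activity makes a respondent a *leaser*; otherwise any boarded
#' equid makes them a *boarder*; otherwise an at-home owner.  (An owner who
#' also leases is a leaser.)  Records with all counts zero or missing cannot
#' be classified.
#'
#' @param records respondent data.frame.
#' @param on_unclassifiable `"error"` (default) or `"na"` to return `NA` for
#'   such records (they are reported via the `"n_unclassifiable"` attribute).
#' @return character vector `"owner"`/`"boarder"`/`"leaser"` per record.
#' @examples
#' r <- data.frame(owns_at_home_count = c("2-4", "1", "0"),
#'                 boards_count = c("0", "0", "2-4"),
#'                 leases_count = c("1", "0", "0"))
#' classify_respondent(r) # leaser, owner, boarder
#' @export
classify_respondent <- function(records, on_unclassifiable = c("error", "na")) {
  on_unclassifiable <- match.arg(on_unclassifiable)
  pos <- function(bin) !is.na(bin) & bin != "0"
  leases <- pos(.check_bin(records$leases_count, "leases_count"))
  boards <- pos(.check_bin(records$boards_count, "boards_count"))
  owns <- pos(.check_bin(records$owns_at_home_count, "owns_at_home_count"))
  out <- ifelse(leases, "leaser", ifelse(boards, "boarder", ifelse(owns, "owner", NA)))
  if (anyNA(out)) {
    if (on_unclassifiable == "error") {
      stop("record(s) with no equids owned, boarded or leased cannot be ",
           "classified: rows ", paste(utils::head(which(is.na(out)), 10), collapse = ", "))
    }
    message(sum(is.na(out)), " unclassifiable record(s) set to NA")
  }
  structure(out, n_unclassifiable = sum(is.na(out)))
}

#' Bin a free-text "other" lease/board description
#'
#' Keyword-rule mapping of free-text "other" answers onto the free / partial /
#' full classification; text matching no rule stays `"unresolvable"` and such
#' respondents contribute 0 to both the partial and full indicators (the
#' model baseline).
#'
#' @param text character vector of free-text descriptions.
#' @param rules ordered list of `list(pattern = <regex>, level = <class>)`;
#'   the first matching rule wins.  Defaults to [default_bin_rules()].
#' @return character vector over `"free"`, `"partial"`, `"full"`,
#'   `"unresolvable"`.
#' @examples
#' bin_other_type("no cost, I just ride her")  # "free"
#' bin_other_type("I pay everything, sole use") # "full"
#' bin_other_type("barter chores for stall")    # "unresolvable"
#' @export
bin_other_type <- function(text, rules = default_bin_rules()) {
  vapply(text, function(tx) {
    if (is.na(tx)) return("unresolvable")
    for (r in rules) {
      if (grepl(r$pattern, tx, ignore.case = TRUE)) return(r$level)
    }
    "unresolvable"
  }, character(1), USE.NAMES = FALSE)
}

#' Default keyword rules for binning "other" lease/board text
#'
#' Mirrors the survey's printed definitions: free = no cost for use of the
#' animal/facility; full = cost permits sole use / covers all care; partial =
#' some cost, animal or facility shared.
#' @return ordered list of pattern/level rules.
#' @export
default_bin_rules <- function() {
  list(
    list(pattern = "no cost|free|no charge|don'?t pay|do not pay|nothing", level = "free"),
    list(pattern = "sole use|everything|all (the )?cost|entire|full", level = "full"),
    list(pattern = "some cost|shared?|split|half|partial", level = "partial")
  )
}

#' Model covariates for each respondent group
#'
#' Names and order of the slope covariates entering each group's interval
#' regression (the intercept is added at fit time).  All three models share
#' the current cost, equid-count, pandemic-impact, sale/stop-lease intent and
#' demographic terms; boarders add board-type and discipline terms, leasers
#' add lease-type and leaser-who-owns terms, owners add discipline terms.
#'
#' @param group `"owner"`, `"boarder"` or `"leaser"`.
#' @return character vector of covariate names.
#' @export
model_covariates <- function(group = c("owner", "boarder", "leaser")) {
  group <- match.arg(group)
  common_pre <- c("current_cost", "own_lease_2_4", "own_lease_5p")
  common_post <- c("covid_less_stable", "covid_more_stable", "sell_yes",
                   "sell_maybe", "south", "ahi_gt_75k", "age_lt_35")
  disciplines <- c("sport", "ranch_western", "other_disciplines")
  switch(group,
    owner = c(common_pre, disciplines, common_post),
    boarder = c(common_pre, c("partial_board_or_lease", "full_board_or_lease"),
                disciplines, common_post),
    leaser = c(common_pre, "leaser_who_owns",
               c("partial_board_or_lease", "full_board_or_lease"), common_post)
  )
}

#' Encode a respondent record into model covariates
#'
#' Binary (0/1) coding of the survey responses for one group's model:
#' equid-count bins collapse `"5-9"`, `"10-19"`, `"20+"` into a single
#' `own_lease_5p` indicator (the count category used is the one defining the
#' group: at-home equids for owners, boarded for boarders, leased for
#' leasers); `south = 1` for the 16 Census-South states; `ahi_gt_75k = 1` for
#' income brackets above $75,000; `age_lt_35 = 1` for the 18-24 and 25-34
#' brackets; the partial/full indicators come from the lease type for
#' leasers and the board type for boarders (`"other"`/`"none"`/`"free"` are
#' baseline).  Missing income, age or pandemic-impact answers propagate as
#' `NA` and are later removed by [listwise_filter()].
#'
#' @param records respondent data.frame (see [survey_schema]).
#' @param group which model to encode for.
#' @return data.frame with columns [model_covariates()] in order.
#' @export
encode_covariates <- function(records, group = c("owner", "boarder", "leaser")) {
  group <- match.arg(group)
  count_col <- switch(group, owner = "owns_at_home_count",
                      boarder = "boards_count", leaser = "leases_count")
  bin <- records[[count_col]]
  type_col <- switch(group, boarder = "board_type", leaser = "lease_type", NULL)
  out <- data.frame(
    current_cost = records$current_cost,
    own_lease_2_4 = as.numeric(bin == "2-4"),
    own_lease_5p = as.numeric(bin %in% c("5-9", "10-19", "20+")),
    covid_less_stable = as.numeric(records$covid_stability == "less"),
    covid_more_stable = as.numeric(records$covid_stability == "more"),
    sell_yes = as.numeric(records$sell_or_stop_intent == "yes"),
    sell_maybe = as.numeric(records$sell_or_stop_intent == "maybe"),
    south = as.numeric(records$region == "south"),
    ahi_gt_75k = as.numeric(records$income_bracket %in% c("75-100k", "100-150k", ">150k")),
    age_lt_35 = as.numeric(records$age_bracket %in% c("18-24", "25-34"))
  )
  out$ahi_gt_75k[is.na(records$income_bracket)] <- NA
  out$age_lt_35[is.na(records$age_bracket)] <- NA
  if (group %in% c("owner", "boarder")) {
    out$sport <- records$disc_sport
    out$ranch_western <- records$disc_ranch_western
    out$other_disciplines <- records$disc_other
  }
  if (!is.null(type_col)) {
    ty <- records[[type_col]]
    out$partial_board_or_lease <- as.numeric(!is.na(ty) & ty == "partial")
    out$full_board_or_lease <- as.numeric(!is.na(ty) & ty == "full")
  }
  if (group == "leaser") {
    pos <- function(b) !is.na(b) & b != "0"
    out$leaser_who_owns <- as.numeric(pos(records$owns_at_home_count) |
                                        pos(records$boards_count))
  }
  out[, model_covariates(group), drop = FALSE]
}

#' Listwise-delete incomplete records for estimation
#'
#' Keeps only records with every model covariate, both bid responses, the
#' follow-up fraction and the current cost present; records per-field counts
#' of the missingness that caused each drop.
#'
#' @param records respondent data.frame.
#' @param covars covariate data.frame from [encode_covariates()], row-aligned
#'   with `records`.
#' @return list with `records`, `covars` (both filtered), `n_dropped`, and
#'   `dropped_by_field` (named integer vector; a record can count towards
#'   several fields).
#' @export
listwise_filter <- function(records, covars) {
  stopifnot(nrow(records) == nrow(covars))
  need <- cbind(
    covars,
    response1 = ifelse(is.na(records$response1), NA, 1),
    response2 = ifelse(is.na(records$response2), NA, 1),
    followup_frac = records$followup_frac,
    current_cost = records$current_cost
  )
  miss <- is.na(need)
  keep <- rowSums(miss) == 0
  if (!any(keep)) stop("no complete records remain after listwise deletion")
  by_field <- colSums(miss[!keep, , drop = FALSE])
  list(
    records = records[keep, , drop = FALSE],
    covars = covars[keep, , drop = FALSE],
    n_dropped = sum(!keep),
    dropped_by_field = by_field[by_field > 0]
  )
}

#' Summarize a numeric survey variable
#'
#' Sample mean, standard deviation (n-1 denominator), minimum, maximum and n,
#' the format of the survey's descriptive tables.  A single observation
#' reports `sd = 0` with a warning rather than `NA`.
#'
#' @param x numeric vector (missing values removed).
#' @param name variable label.
#' @return one-row data.frame with `variable`, `n`, `mean`, `sd`, `min`, `max`.
#' @examples
#' summarize_variable(c(100, 300)) # mean 200, sd 141.42
#' @export
summarize_variable <- function(x, name = deparse(substitute(x))) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("cannot summarize an empty group")
  s <- if (length(x) == 1) {
    warning("single observation: reporting sd = 0")
    0
  } else stats::sd(x)
  data.frame(variable = name, n = length(x), mean = mean(x), sd = s,
             min = min(x), max = max(x), stringsAsFactors = FALSE)
}

#' Proportions of the four response sequences
#'
#' Share of each (response1, response2) sequence among the given records:
#' the number of observations in each sequence divided by the total.
#'
#' @param response1,response2 `"yes"`/`"no"` vectors (pairs with missing
#'   entries are dropped).
#' @return named numeric vector `yes_yes`, `yes_no`, `no_yes`, `no_no`
#'   summing to 1.
#' @export
sequence_proportions <- function(response1, response2) {
  ok <- !is.na(response1) & !is.na(response2)
  r1 <- response1[ok]; r2 <- response2[ok]
  if (length(r1) == 0) stop("no complete response pairs")
  key <- paste(r1, r2, sep = "_")
  levels <- c("yes_yes", "yes_no", "no_yes", "no_no")
  counts <- vapply(levels, function(l) sum(key == l), numeric(1))
  counts / length(r1)
}

#' Pooled-variance two-sample Student t-test
#'
#' Two-sided mean comparison with the classical equal-variance pooling.
#' The degenerate case of zero pooled variance returns `t = 0, p = 1` when
#' the group means are equal and is an error otherwise (the difference is
#' then certain and no t-scale exists).
#'
#' @param a,b numeric vectors, each with at least 2 observations.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 observations")
  df <- length(a) + length(b) - 2
  pooled <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df
  if (pooled == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = df, p = 1))
    stop("zero pooled variance with unequal means: t statistic undefined")
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
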