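#' Excitatory rate of a drug response
#'
#' The percent change in mean firing rate between a post-injection response
#' window and the 30-min baseline immediately preceding the injection:
#' `E = 100 * (response_rate - baseline_rate) / baseline_rate`. The
#' response window is the first 10 min after a Kiss-10 injection and the
#' 30 min following a CNO-containing injection.
#'
#' @param train a [spike_train()]
#' @param t_inj injection time, session seconds (must allow a full
#'   baseline window before it)
#' @param response_len response window length, seconds (600 for Kiss-10,
#'   1800 for CNO-containing injections)
#' @param baseline_len baseline window length, seconds (default 1800)
#' @return list with `E` (percent), `baseline_rate`, `response_rate` (Hz),
#'   `baseline_window`, `response_window`
#' @export
excitatory_rate <- function(train, t_inj, response_len = 600,
                            baseline_len = 1800) {
  stopifnot(inherits(train, "spike_train"), response_len > 0,
            baseline_len > 0)
  if (t_inj < baseline_len)
    stop("injection at ", t_inj, " s leaves no room for a ", baseline_len,
         " s baseline window")
  base_rate <- mean_rate(train, t_inj - baseline_len, t_inj)
  # response window (t_inj, t_inj + response_len]
  resp_n <- sum(train$timestamps > t_inj &
                  train$timestamps <= t_inj + response_len)
  resp_rate <- resp_n / response_len
  if (base_rate == 0)
    stop("zero baseline rate: excitatory rate undefined for unit ",
         train$unit_id)
  list(E = 100 * (resp_rate - base_rate) / base_rate,
       baseline_rate = base_rate, response_rate = resp_rate,
       baseline_window = c(t_inj - baseline_len, t_inj),
       response_window = c(t_inj, t_inj + response_len))
}

#' Classify a unit under the hM4D(Gi) dual criterion
#'
#' A unit is accepted as a GnRH neuron when Kiss-10 excites it
#' (`E_kiss > alpha`) and prior CNO suppresses that excitation by more
#' than `alpha` percent: `R = 100 * (E_kiss - E_second) / E_kiss > alpha`.
#' Both inequalities are strict. When `require_kiss_excitation = FALSE`
#' the first test relaxes to `E_kiss > 0` (any activation).
#'
#' @param E_kiss excitatory rate of the first Kiss-10 injection, percent
#' @param E_second excitatory rate of the Kiss-10+CNO co-injection, percent
#' @param alpha criterion threshold, percent (default 40)
#' @param require_kiss_excitation require `E_kiss > alpha` rather than
#'   just `E_kiss > 0`
#' @return list with `is_gnrh`, `model = "gi"`, `E_kiss`, `E_second`,
#'   `reduction` (R, percent; NA when `E_kiss <= 0`), `alpha`
#' @export
classify_gi <- function(E_kiss, E_second, alpha = 40,
                        require_kiss_excitation = TRUE) {
  stopifnot(is.finite(E_kiss), is.finite(E_second), alpha >= 0)
  if (E_kiss <= 0)
    return(list(is_gnrh = FALSE, model = "gi", E_kiss = E_kiss,
                E_second = E_second, reduction = NA_real_, alpha = alpha))
  R <- 100 * (E_kiss - E_second) / E_kiss
  first_ok <- if (require_kiss_excitation) E_kiss > alpha else E_kiss > 0
  list(is_gnrh = first_ok && R > alpha, model = "gi", E_kiss = E_kiss,
       E_second = E_second, reduction = R, alpha = alpha)
}

#' Classify a unit under the hM3D(Gq) dual criterion
#'
#' A unit is accepted as a GnRH neuron when both the Kiss-10 and the CNO
#' excitatory rates exceed `alpha` percent of the basal rate (strict
#' inequalities).
#'
#' @param E_kiss,E_cno excitatory rates in percent
#' @param alpha criterion threshold, percent (default 40)
#' @return list with `is_gnrh`, `model = "gq"`, `E_kiss`, `E_second`,
#'   `alpha`
#' @export
classify_gq <- function(E_kiss, E_cno, alpha = 40) {
  stopifnot(is.finite(E_kiss), is.finite(E_cno), alpha >= 0)
  list(is_gnrh = E_kiss > alpha && E_cno > alpha, model = "gq",
       E_kiss = E_kiss, E_second = E_cno, alpha = alpha)
}

#' Identify GnRH neurons across a cohort of sessions
#'
#' Applies [excitatory_rate()] to each session's injection sequence and
#' the model's dual criterion to each unit. Kiss-10 responses are scored
#' over the first 10 min; CNO-containing responses over 30 min; the
#' baseline for each score is the 30 min immediately preceding that
#' injection. Sessions missing the required injections, or with a zero
#' baseline, are skipped with a warning and excluded from the summary
#' denominator of classified units only (they still count as recorded).
#'
#' @param sessions list of [gnrh_session()] (one unit each), e.g. from
#'   [generate_cohort()]
#' @param model "gi" or "gq"
#' @param alpha criterion threshold, percent
#' @param ... passed to [classify_gi()]
#' @return list with `classifications` (one row per unit: unit_id, E_kiss,
#'   E_second, reduction, is_gnrh), `fraction` (identified / total
#'   recorded units), `n_identified`, `n_units`
#' @export
identify_cohort <- function(sessions, model = c("gi", "gq"), alpha = 40,
                            ...) {
  model <- match.arg(model)
  second_drug <- if (model == "gi") "Kiss10+CNO" else "CNO"
  rows <- lapply(sessions, function(s) {
    stopifnot(inherits(s, "gnrh_session"))
    train <- s$trains[[1L]]
    inj <- s$events$injections
    t_kiss <- inj$t_s[inj$drug == "Kiss10"][1L]
    t_second <- inj$t_s[inj$drug == second_drug][1L]
    if (is.na(t_kiss) || is.na(t_second)) {
      warning("unit ", train$unit_id, ": missing ", model,
              " injection sequence; skipped")
      return(data.frame(unit_id = train$unit_id, E_kiss = NA_real_,
                        E_second = NA_real_, reduction = NA_real_,
                        is_gnrh = NA))
    }
    res <- tryCatch({
      ek <- excitatory_rate(train, t_kiss, response_len = 600)$E
      e2 <- excitatory_rate(train, t_second, response_len = 1800)$E
      cls <- if (model == "gi") classify_gi(ek, e2, alpha, ...) else
        classify_gq(ek, e2, alpha)
      data.frame(unit_id = train$unit_id, E_kiss = ek, E_second = e2,
                 reduction = if (model == "gi") cls$reduction else NA_real_,
                 is_gnrh = cls$is_gnrh)
    }, error = function(e) {
      warning("unit ", train$unit_id, ": ", conditionMessage(e),
              "; unclassifiable")
      data.frame(unit_id = train$unit_id, E_kiss = NA_real_,
                 E_second = NA_real_, reduction = NA_real_, is_gnrh = NA)
    })
    res
  })
  cls <- do.call(rbind, rows)
  n_id <- sum(cls$is_gnrh, na.rm = TRUE)
  list(classifications = cls,
       fraction = if (length(sessions)) n_id / length(sessions) else NaN,
       n_identified = n_id, n_units = length(sessions))
}
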