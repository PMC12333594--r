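#' Simulate behavioral response tables
#'
#' Emulates the deception game's behavior: per participant pair, 11 sessions
#' of 44 trials (22 spontaneous, 11 instructed-lie, 11 instructed-truth in
#' shuffled order). In spontaneous trials the player lies with a per-pair
#' probability drawn uniformly from `lying_range` (defaults mirror the
#' observed 30-65% spread); the observer responds trust/untrust at chance,
#' reproducing a null behavioral structure in which accuracy hovers at 50%.
#'
#' @param n_pairs Number of participant pairs (observers).
#' @param n_sessions Sessions per pair.
#' @param trials_per_session Trials per session (multiple of 4).
#' @param lying_range Range of per-pair spontaneous lying probability.
#' @param seed Integer seed.
#' @return A tibble: `subject`, `session`, `trial`, `condition`
#'   (spontaneous / instructed_lie / instructed_truth), `player_action`
#'   (lie / truth), `observer_response` (trust / untrust), `correct`.
#' @export
simulate_responses <- function(n_pairs = 23, n_sessions = 11,
                               trials_per_session = 44,
                               lying_range = c(0.30, 0.65), seed = 1L) {
  stopifnot(trials_per_session %% 4 == 0)
  k <- trials_per_session / 4
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_pairs), function(pr) {
      p_lie <- stats::runif(1, lying_range[1L], lying_range[2L])
      purrr::map_dfr(seq_len(n_sessions), function(se) {
        condition <- sample(rep(c("spontaneous", "instructed_lie",
                                  "instructed_truth"), times = c(2 * k, k, k)))
        action <- ifelse(
          condition == "instructed_lie", "lie",
          ifelse(condition == "instructed_truth", "truth",
                 ifelse(stats::runif(trials_per_session) < p_lie, "lie", "truth"))
        )
        response <- sample(c("trust", "untrust"), trials_per_session,
                           replace = TRUE)
        tibble::tibble(
          subject = sprintf("pair%02d", pr),
          session = se,
          trial = seq_len(trials_per_session),
          condition = condition,
          player_action = action,
          observer_response = response,
          correct = (response == "trust" & action == "truth") |
            (response == "untrust" & action == "lie")
        )
      })
    })
  })
}

#' Observer accuracy against chance
#'
#' Per-subject accuracy entered into a one-sample t-test against the 50%
#' chance level.
#'
#' @param table A response tibble as from [simulate_responses()].
#' @return A tibble: `mean_accuracy`, `sd_accuracy`, `t`, `df`, `p`.
#' @export
accuracy_vs_chance <- function(table) {
  acc <- dplyr::summarise(dplyr::group_by(table, .data$subject),
                          accuracy = mean(.data$correct), .groups = "drop")
  if (nrow(acc) < 2L) stop("need at least 2 subjects", call. = FALSE)
  tt <- stats::t.test(acc$accuracy, mu = 0.5)
  tibble::tibble(
    mean_accuracy = mean(acc$accuracy),
    sd_accuracy = stats::sd(acc$accuracy),
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value
  )
}

#' Repeated-measures ANOVA of accuracy over sessions
#'
#' @param table A response tibble as from [simulate_responses()].
#' @return An `rm_anova` tibble: `effect`, `F`, `df1`, `df2`, `p`, `eta_p2`.
#' @export
session_accuracy_anova <- function(table) {
  acc <- dplyr::summarise(dplyr::group_by(table, .data$subject, .data$session),
                          accuracy = mean(.data$correct), .groups = "drop")
  full <- length(unique(acc$subject)) * length(unique(acc$session))
  if (nrow(acc) != full) stop("incomplete subject x session grid", call. = FALSE)
  rm_anova_1f(acc, dv = "accuracy", within = "session", id = "subject")
}

#' Correlation of observer accuracy with player lying proportion
#'
#' Pearson correlation, across participant pairs, between the observer's
#' overall accuracy and the player's proportion of lies in spontaneous
#' trials.
#'
#' @param table A response tibble as from [simulate_responses()].
#' @return A tibble: `r`, `df`, `p`.
#' @export
lying_proportion_regression <- function(table) {
  per_pair <- dplyr::summarise(
    dplyr::group_by(table, .data$subject),
    accuracy = mean(.data$correct),
    lying = mean(.data$player_action[.data$condition == "spontaneous"] == "lie"),
    .groups = "drop"
  )
  if (nrow(per_pair) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(per_pair$lying) == 0 || stats::sd(per_pair$accuracy) == 0) {
    stop("degenerate variance: accuracy or lying proportion constant",
         call. = FALSE)
  }
  ct <- stats::cor.test(per_pair$accuracy, per_pair$lying)
  tibble::tibble(r = unname(ct$estimate), df = unname(ct$parameter),
                 p = ct$p.value)
}
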