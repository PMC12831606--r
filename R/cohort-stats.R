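#' Exact Wilcoxon signed-rank test on paired per-animal values
#'
#' Two-sided paired signed-rank test. Zero differences are dropped
#' (Wilcoxon's original convention; implementations differ, so this is
#' pinned). With no ties among the absolute differences and at most
#' `exact_max` informative pairs the p-value comes from the exact signed-rank
#' distribution; otherwise the normal approximation with tie correction and
#' continuity correction is used. The reported `statistic` is the signed
#' rank sum `V_pos - V_neg` (positive when `a` tends to exceed `b`), so
#' swapping `a` and `b` flips its sign and leaves the p-value unchanged.
#'
#' @param a,b Paired numeric vectors (e.g. per-animal trial-10 and trial-1
#'   responses).
#' @param exact_max Largest number of informative pairs for which the exact
#'   distribution is used (default 25).
#' @param zero_tol Differences with absolute value at or below this are
#'   treated as zeros and dropped. The default 1e-12 makes the zero-drop
#'   convention robust to floating-point noise in computed responses
#'   (which are order-1 quantities); set to 0 for strict equality.
#' @return A tibble `statistic`, `v` (rank sum of positive differences),
#'   `p_value`, `n_used`, `method`, `undefined` (TRUE when all differences
#'   are zero — the test is flagged undefined, `p_value` is `NA`).
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 25, zero_tol = 1e-12) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[!is.na(d)]
  d <- d[abs(d) > zero_tol]
  n <- length(d)
  if (n == 0) {
    return(tibble(statistic = NA_real_, v = NA_real_, p_value = NA_real_,
                  n_used = 0L, method = "undefined",
                  undefined = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  statistic <- v - sum(r[d < 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= exact_max) {
    p <- 2 * min(psignrank(v, n), 1 - psignrank(v - 1, n))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  tibble(statistic = statistic, v = v, p_value = p, n_used = n,
         method = method, undefined = FALSE)
}

#' Kruskal-Wallis rank-sum test across groups of per-animal values
#'
#' Thin tabular wrapper around the rank-based H test with tie correction
#' and chi-square p-value.
#'
#' @param data A data frame.
#' @param value,group Column names (tidy-eval) holding the values and group
#'   memberships.
#' @return A tibble `statistic` (H), `df`, `p_value`, `n_groups`.
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  if (nlevels(droplevels(g)) < 2) {
    abort("Kruskal-Wallis requires at least two groups.",
          class = "optodesens_argument_error")
  }
  kt <- kruskal.test(v, g)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, n_groups = nlevels(droplevels(g)))
}

#' Per-class population responses for one session
#'
#' Runs the quantification chain on a session: stimulus-triggered
#' delta-F/F, target assignment, responsiveness screening of targets,
#' optional network classification, and the per-trial population response
#' (AUC of the mean delta-F/F over the 1 s post-stimulation) for each cell
#' class. Excited cells are additionally split by ground-truth opsin
#' expression (`excited_opsin_pos` / `excited_opsin_neg`) when the session
#' carries a population table.
#'
#' @param session An `opto_session`.
#' @param network Classify the non-target network? If `FALSE`, only the
#'   target class is scored (faster).
#' @param alpha Significance level for network classification.
#' @param dff Optional precomputed [trial_dff()].
#' @return A list with `responses` (tibble `class`, `trial`, `response`,
#'   `n_cells`, `valid`), `labels` (the partition), `responsive` (the
#'   responsiveness screen).
#' @export
analyze_session <- function(session, network = TRUE, alpha = 0.05,
                            dff = NULL) {
  if (is.null(dff)) dff <- trial_dff(session, pre = 1, post = 2)
  resp <- is_responsive(dff)
  if (network) {
    labels <- classify_cells(session, dff = dff, alpha = alpha)
  } else {
    ta <- assign_targets(session$beamlets, session$population)
    labels <- mutate(ta, label = ifelse(.data$label == "none",
                                        "non_responder", .data$label),
                     r = NA_real_, p_all = NA_real_, p_trial1 = NA_real_,
                     target = NA_integer_)
  }
  responsive_cells <- resp$cell[resp$responsive]
  subsets <- list(
    target = intersect(labels$cell[labels$label == "target"],
                       responsive_cells)
  )
  if (network) {
    subsets$excited <- labels$cell[labels$label == "excited"]
    subsets$inhibited <- labels$cell[labels$label == "inhibited"]
    subsets$non_responder <- labels$cell[labels$label == "non_responder"]
    if (!is.null(session$population$opsin)) {
      ops <- session$population$cell[session$population$opsin]
      subsets$excited_opsin_pos <- intersect(subsets$excited, ops)
      subsets$excited_opsin_neg <- setdiff(subsets$excited, ops)
    }
  }
  responses <- list_rbind(imap(subsets, function(cells, cls) {
    r <- suppressWarnings(population_response(dff, cells = cells))
    mutate(r, class = cls)
  }))
  list(responses = select(responses, "class", "trial", "response",
                          "n_cells", "valid"),
       labels = labels, responsive = resp)
}

#' Per-trial responses for every session of a cohort
#'
#' @param cohort A [generate_cohort()] tibble (columns `animal`,
#'   `condition`, `isi`, `dose_mode`, `dose_duration`, `session`).
#' @param network Classify the non-target network in each session?
#' @param alpha Significance level for network classification.
#' @return A tibble `animal`, `condition`, `isi`, `dose_mode`, `class`,
#'   `trial`, `response`, `n_cells`, `valid`.
#' @export
cohort_responses <- function(cohort, network = TRUE, alpha = 0.05) {
  list_rbind(map(seq_len(nrow(cohort)), function(i) {
    res <- analyze_session(cohort$session[[i]], network = network,
                           alpha = alpha)
    mutate(res$responses, animal = cohort$animal[i],
           condition = cohort$condition[i], isi = cohort$isi[i],
           dose_mode = cohort$dose_mode[i], .before = 1)
  }))
}

# Mean response per animal x trial within a class, averaged over the given
# conditions first (animals are the statistical unit throughout).
animal_means <- function(responses, cls, by = NULL) {
  d <- filter(responses, .data$class == cls, .data$valid)
  grp <- c("animal", by, "trial")
  summarize(group_by(d, across(all_of(grp))),
            response = mean(.data$response), .groups = "drop")
}

# delta_response on only those groups that actually carry both trials
# (subset classes can be empty in some conditions; those cells are dropped
# rather than erroring the whole battery).
safe_delta <- function(am, first, last) {
  keys <- setdiff(names(am), c("trial", "response"))
  ok <- summarize(group_by(am, across(all_of(keys))),
                  ok = sum(.data$trial == first) == 1 &
                       sum(.data$trial == last) == 1,
                  .groups = "drop")
  kept <- semi_join(am, filter(ok, .data$ok), by = keys)
  if (nrow(kept) == 0) return(NULL)
  delta_response(kept, first = first, last = last)
}

paired_trial_test <- function(am, first = 1, last = 10) {
  wide <- tidyr::pivot_wider(filter(am, .data$trial %in% c(first, last)),
                             names_from = "trial", values_from = "response",
                             names_prefix = "t")
  wilcoxon_signed_rank(wide[[paste0("t", last)]],
                       wide[[paste0("t", first)]])
}

#' Run the full cohort comparison battery
#'
#' Aggregates a cohort's per-session responses with the animal as the
#' statistical unit and runs the grouped comparisons of the desensitization
#' analysis: per-class decay curves (averaged across ISIs then animals,
#' normalized to trial 1), trial-1 vs trial-10 signed-rank tests per dose
#' (averaged across ISIs), per ISI (averaged across doses) and per
#' condition, delta-response-vs-ISI linear fits per class and dose, a
#' paired dose comparison of delta-response, a Kruskal-Wallis test of
#' first-trial responses across doses, and the opsin+/opsin- excited-cell
#' delta-response comparison. Deterministic given the cohort; no
#' multiple-comparison correction is applied across the grid (per-comparison
#' p-values are reported).
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param responses Optional precomputed [cohort_responses()].
#' @param classes Cell classes to analyze.
#' @return An object of class `grid_analysis`: list of tibbles
#'   (`responses`, `decay_curves`, `trial_tests_by_dose`,
#'   `trial_tests_by_isi`, `trial_tests_by_condition`, `delta_vs_isi`,
#'   `dose_comparison`, `first_trial_kw`, `opsin_comparison`).
#' @export
run_grid_analysis <- function(cohort, responses = NULL,
                              classes = c("target", "excited", "inhibited",
                                          "non_responder")) {
  if (is.null(responses)) responses <- cohort_responses(cohort)
  classes <- intersect(classes, unique(responses$class))
  isis <- sort(unique(responses$isi))
  doses <- unique(responses$dose_mode)
  n_trials <- max(responses$trial)

  decay_curves <- list_rbind(map(classes, function(cls) {
    list_rbind(map(doses, function(dm) {
      d <- filter(responses, .data$class == cls, .data$dose_mode == dm,
                  .data$valid)
      curve <- tryCatch(
        normalized_decay_curve(select(d, "animal", "isi", "trial",
                                      "response")),
        error = function(e) NULL)
      if (is.null(curve)) return(NULL)
      mutate(curve, class = cls, dose_mode = dm, .before = 1)
    }))
  }))

  trial_tests_by_dose <- list_rbind(map(classes, function(cls) {
    list_rbind(map(doses, function(dm) {
      am <- animal_means(filter(responses, .data$dose_mode == dm), cls)
      mutate(paired_trial_test(am, 1, n_trials), class = cls,
             dose_mode = dm, .before = 1)
    }))
  }))

  trial_tests_by_isi <- list_rbind(map(classes, function(cls) {
    list_rbind(map(isis, function(ii) {
      am <- animal_means(filter(responses, .data$isi == ii), cls)
      mutate(paired_trial_test(am, 1, n_trials), class = cls, isi = ii,
             .before = 1)
    }))
  }))

  trial_tests_by_condition <- list_rbind(map(classes, function(cls) {
    list_rbind(map(unique(responses$condition), function(cn) {
      am <- animal_means(filter(responses, .data$condition == cn), cls)
      mutate(paired_trial_test(am, 1, n_trials), class = cls,
             condition = cn, .before = 1)
    }))
  }))

  # delta response per animal x isi x dose x class
  deltas <- list_rbind(map(classes, function(cls) {
    am <- animal_means(responses, cls, by = c("isi", "dose_mode"))
    d <- safe_delta(am, 1, n_trials)
    if (is.null(d)) return(NULL)
    mutate(d, class = cls, .before = 1)
  }))

  delta_vs_isi <- list_rbind(map(classes, function(cls) {
    list_rbind(map(doses, function(dm) {
      d <- filter(deltas, .data$class == cls, .data$dose_mode == dm)
      mean_d <- summarize(group_by(d, .data$isi),
                          delta_response = mean(.data$delta_response),
                          .groups = "drop")
      if (nrow(mean_d) < 2) return(NULL)
      fit <- fit_linear(mean_d$isi, mean_d$delta_response)
      tibble(class = cls, dose_mode = dm,
             slope = coef(fit)[["slope"]],
             intercept = coef(fit)[["intercept"]], rss = fit$rss)
    }))
  }))

  dose_comparison <- if (length(doses) < 2) {
    NULL
  } else if (length(doses) == 2) {
    list_rbind(map(classes, function(cls) {
      d <- summarize(group_by(filter(deltas, .data$class == cls),
                              .data$animal, .data$dose_mode),
                     delta_response = mean(.data$delta_response),
                     .groups = "drop")
      wide <- tidyr::pivot_wider(d, names_from = "dose_mode",
                                 values_from = "delta_response")
      if (!all(doses %in% names(wide))) return(NULL)
      mutate(wilcoxon_signed_rank(wide[[doses[1]]], wide[[doses[2]]]),
             class = cls, comparison = paste(doses, collapse = " vs "),
             .before = 1)
    }))
  } else {
    kw_in <- summarize(group_by(deltas, .data$class, .data$animal,
                                .data$dose_mode),
                       delta_response = mean(.data$delta_response),
                       .groups = "drop")
    list_rbind(map(classes, function(cls) {
      mutate(kruskal_wallis(filter(kw_in, .data$class == cls),
                            "delta_response", "dose_mode"),
             class = cls, .before = 1)
    }))
  }

  first_trial <- filter(responses, .data$trial == 1, .data$valid,
                        .data$class == "target")
  first_trial_am <- summarize(group_by(first_trial, .data$animal,
                                       .data$dose_mode),
                              response = mean(.data$response),
                              .groups = "drop")
  first_trial_kw <- if (length(doses) >= 2) {
    kruskal_wallis(first_trial_am, "response", "dose_mode")
  } else NULL

  opsin_comparison <- NULL
  if (all(c("excited_opsin_pos", "excited_opsin_neg") %in%
          unique(responses$class))) {
    pos <- safe_delta(animal_means(responses, "excited_opsin_pos",
                                   by = c("isi", "dose_mode")), 1, n_trials)
    neg <- safe_delta(animal_means(responses, "excited_opsin_neg",
                                   by = c("isi", "dose_mode")), 1, n_trials)
    if (!is.null(pos) && !is.null(neg)) {
      dp <- summarize(group_by(pos, .data$animal),
                      delta_response = mean(.data$delta_response),
                      .groups = "drop")
      dn <- summarize(group_by(neg, .data$animal),
                      delta_response = mean(.data$delta_response),
                      .groups = "drop")
      joined <- inner_join(dp, dn, by = "animal",
                           suffix = c("_opsin_pos", "_opsin_neg"))
      if (nrow(joined) > 0) {
        opsin_comparison <- wilcoxon_signed_rank(
          joined$delta_response_opsin_pos, joined$delta_response_opsin_neg)
      }
    }
  }

  structure(
    list(responses = responses, decay_curves = decay_curves,
         trial_tests_by_dose = trial_tests_by_dose,
         trial_tests_by_isi = trial_tests_by_isi,
         trial_tests_by_condition = trial_tests_by_condition,
         deltas = deltas, delta_vs_isi = delta_vs_isi,
         dose_comparison = dose_comparison,
         first_trial_kw = first_trial_kw,
         opsin_comparison = opsin_comparison),
    class = "grid_analysis"
  )
}

#' @export
print.grid_analysis <- function(x, ...) {
  cat("<grid_analysis>\n")
  cat(sprintf("  %d response rows over %d animals, %d conditions\n",
              nrow(x$responses), length(unique(x$responses$animal)),
              length(unique(x$responses$condition))))
  cat("  components: decay_curves, trial_tests_by_{dose,isi,condition},\n",
      "             deltas, delta_vs_isi, dose_comparison, first_trial_kw,\n",
      "             opsin_comparison\n")
  invisible(x)
}
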