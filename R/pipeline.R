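#' Run the full simulated experiment end to end
#'
#' Simulates EEG epochs, pairwise choices and willingness-to-pay bids from
#' one ground truth, scores the behaviour into a preference profile,
#' applies the ERP pipeline (baseline correction, optional band-pass,
#' amplitude-based artifact rejection, minimum-trial participant
#' inclusion), runs the single-item discrimination analysis and the
#' group-level repeated-measures ANOVAs, and returns every stage's result.
#' Identical truth (including its seed) gives identical output.
#'
#' @param truth a `simulation_truth`.
#' @param filter apply the optional 0.01-30 Hz zero-phase band-pass
#'   (default off; the generator is already band-limited).
#' @param min_trials minimum artifact-free trials per item for a
#'   participant to be retained.
#' @param fdr_family FDR family for the contrasts ("all" or "per_window").
#' @param alpha significance level.
#' @param exclude_ranks ranks dropped for the exclusion-adjusted accuracy.
#' @param anova do the group-level ANOVAs (slower; skippable when only the
#'   discrimination result is needed).
#' @param out_dir if non-NULL, write intermediate CSVs and a summary JSON
#'   there.
#' @return list with `truth`, `profile`, `behavior`, `rejection`,
#'   `excluded`, `scores`, `discrimination`, `replication`, `summary`.
#' @export
run_pipeline <- function(truth = simulation_truth(), filter = FALSE,
                         min_trials = 16, fdr_family = "all", alpha = 0.05,
                         exclude_ranks = integer(0), anova = TRUE,
                         out_dir = NULL) {
  choices <- simulate_choices(truth)
  wtp <- simulate_wtp(truth)
  profile <- count_choices(choices, n_items = truth$n_items)
  behavior <- list(
    consistency = intersubject_consistency(profile),
    switches = choice_switch_consistency(choices),
    hp_lp = hp_lp_choice_test(profile),
    wtp = wtp_choice_correlation(profile, wtp)
  )

  epochs <- simulate_epochs(truth)
  epochs <- baseline_correct(epochs)
  if (filter) epochs <- filter_epochs(epochs)
  rej <- reject_artifacts(epochs)
  excluded <- enforce_min_trials(rej$report, min_trials = min_trials)
  kept_participants <- setdiff(seq_len(truth$n_participants), excluded)

  traces <- si_roi_traces(epochs, rej$rejected, kept_participants)
  scores <- si_component_scores(traces, profile)
  disc <- discriminate(scores, family = fdr_family, alpha = alpha,
                       exclude_ranks = exclude_ranks)

  replication <- NULL
  if (anova) {
    es <- electrode_scores(epochs, si_windows(), rej$rejected,
                           kept_participants)
    replication <- lapply(si_windows(), function(ms) {
      cells <- build_cells(es[es$measure == ms, ], profile)
      list(measure = ms, anova = rm_anova(cells),
           simple_ap = simple_effects(cells, "AP"))
    })
    names(replication) <- si_windows()
    late <- setdiff(si_windows(), "n200")
    p_late <- vapply(replication[late], function(r)
      r$anova$p_gg[r$anova$effect == "Preference"], numeric(1))
    for (j in seq_along(late))
      replication[[late[j]]]$p_preference_bonferroni <-
        bonferroni_late_windows(p_late)[j]
  }

  summary <- list(
    n_participants = truth$n_participants,
    n_excluded = length(excluded),
    trials_rejected = sum(rej$report$trials_rejected),
    mean_kept_trials = mean(rej$report$trials_kept[
      rej$report$participant %in% kept_participants]),
    behavior = list(r_mean = behavior$consistency$r_mean,
                    switch_mean = behavior$switches$mean,
                    switch_fraction = behavior$switches$fraction,
                    hp_lp_t = behavior$hp_lp$t,
                    wtp_rho = behavior$wtp$rho),
    accuracy = disc$accuracy[c("overall", "by_window", "psw_800_3000")],
    significant_contrasts = mean(disc$contrasts$significant)
  )

  result <- list(truth = truth, profile = profile, behavior = behavior,
                 rejection = rej$report, excluded = excluded,
                 scores = scores, discrimination = disc,
                 replication = replication, summary = summary)
  if (!is.null(out_dir)) write_pipeline_outputs(result, choices, wtp, out_dir)
  result
}

#' Write pipeline artifacts to a directory
#'
#' Choices, bids and the preference profile as CSV with fixed headers, the
#' contrast table and verdict grid as CSV, and the run summary as JSON.
#'
#' @param result list from [run_pipeline()].
#' @param choices,wtp the simulated behavioural records.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(result, choices, wtp, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    choices = file.path(out_dir, "choices.csv"),
    wtp = file.path(out_dir, "wtp.csv"),
    profile = file.path(out_dir, "preference_profile.csv"),
    contrasts = file.path(out_dir, "contrasts.csv"),
    verdicts = file.path(out_dir, "verdicts.csv"),
    summary = file.path(out_dir, "summary.json")
  )
  utils::write.csv(choices[c("participant", "block", "item_a", "item_b",
                             "chosen", "side")],
                   paths["choices"], row.names = FALSE)
  utils::write.csv(wtp[c("participant", "item", "bid", "hidden_price",
                         "purchased")],
                   paths["wtp"], row.names = FALSE)
  prof <- result$profile
  utils::write.csv(data.frame(item = seq_along(prof$group_counts),
                              mean_count = prof$group_counts,
                              rank = prof$ranks, label = prof$labels),
                   paths["profile"], row.names = FALSE)
  utils::write.csv(result$discrimination$contrasts, paths["contrasts"],
                   row.names = FALSE)
  v <- result$discrimination$verdicts
  utils::write.csv(data.frame(rank = rownames(v), v, check.names = FALSE),
                   paths["verdicts"], row.names = FALSE)
  jsonlite::write_json(result$summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
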