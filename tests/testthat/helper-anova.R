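# Builders and the independent aov() oracle for the within-subject ANOVA.

# random balanced cell matrix for n participants
random_cells <- function(n, effect = NULL) {
  v <- array(rnorm(n * 18), dim = c(n, 2, 3, 3),
             dimnames = list(NULL, preference = c("HP", "LP"),
                             ap = c("Anterior", "Central", "Posterior"),
                             lat = c("Left", "Midline", "Right")))
  if (!is.null(effect)) v <- v + effect
  structure(list(values = v, participants = seq_len(n)),
            class = "cell_matrix")
}

cells_to_long <- function(cells) {
  v <- cells$values
  n <- dim(v)[1]
  grid <- expand.grid(subject = seq_len(n), P = c("HP", "LP"),
                      A = c("Anterior", "Central", "Posterior"),
                      L = c("Left", "Midline", "Right"))
  grid$value <- as.vector(v)
  grid$subject <- factor(grid$subject)
  grid
}

# independent route: error-stratified aov() fit on the long data
aov_oracle <- function(cells) {
  long <- cells_to_long(cells)
  fit <- summary(aov(value ~ P * A * L + Error(subject / (P * A * L)),
                     data = long))
  strata <- fit[paste0("Error: subject:",
                       c("P", "A", "L", "P:A", "P:L", "A:L", "P:A:L"))]
  do.call(rbind, lapply(strata, function(s) {
    tab <- s[[1]]
    data.frame(f_stat = tab[1, "F value"], df1 = tab[1, "Df"],
               df2 = tab[2, "Df"], ss_effect = tab[1, "Sum Sq"],
               ss_error = tab[2, "Sum Sq"])
  }))
}

# shared scaled-down study configuration for simulation-heavy checks
scaled_truth <- function(slopes, seed) {
  simulation_truth(n_participants = 12, trials_per_item = 12,
                   sampling_rate = 32, artifact_fraction = 0,
                   component_slopes = slopes, seed = seed)
}

# generator -> ERP pipeline -> discrimination, at the scaled size
run_discrimination <- function(truth, min_trials = 6) {
  ep <- baseline_correct(simulate_epochs(truth))
  rej <- reject_artifacts(ep)
  keep <- setdiff(seq_len(truth$n_participants),
                  enforce_min_trials(rej$report, min_trials))
  traces <- si_roi_traces(ep, rej$rejected, keep)
  profile <- suppressWarnings(count_choices(simulate_choices(truth)))
  discriminate(si_component_scores(traces, profile))
}
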