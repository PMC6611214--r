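#' Score pairwise choices into a preference profile
#'
#' Counts, for every participant, how often each item was chosen across all
#' blocks, averages counts across participants, ranks items from 1 (most
#' preferred) downwards on the group mean, and splits them at the median
#' into highly preferred (HP, ranks 1 to n/2) and less preferred (LP)
#' groups. With 12 items and 7 blocks each participant contributes 462
#' choices and an item can be chosen at most 77 times.
#'
#' @param records data.frame of choice records (`participant`, `block`,
#'   `item_a`, `item_b`, `chosen`, `side`), complete blocks: every unordered
#'   pair exactly once per block.
#' @param n_items number of items in the design.
#' @return a `preference_profile`: list with `counts` (participant x item
#'   matrix), `group_counts` (mean count per item across participants),
#'   `ranks` (1 = most preferred; ties broken by lower item id, with a
#'   warning), `labels` ("HP"/"LP" per item), `n_blocks`.
#' @export
count_choices <- function(records, n_items = max(c(records$item_a, records$item_b))) {
  bad <- records$chosen != records$item_a & records$chosen != records$item_b
  if (any(bad)) {
    r <- records[which(bad)[1], ]
    stop("chosen item not in pair for participant ", r$participant,
         ", block ", r$block, ", pair (", r$item_a, ", ", r$item_b, ")")
  }
  key <- paste(records$participant, records$block,
               pmin(records$item_a, records$item_b),
               pmax(records$item_a, records$item_b))
  if (anyDuplicated(key)) {
    r <- records[which(duplicated(key))[1], ]
    stop("duplicate pair within a block: participant ", r$participant,
         ", block ", r$block, ", pair (", r$item_a, ", ", r$item_b, ")")
  }
  participants <- sort(unique(records$participant))
  counts <- table(factor(records$participant, levels = participants),
                  factor(records$chosen, levels = seq_len(n_items)))
  counts <- matrix(as.integer(counts), nrow = length(participants),
                   dimnames = list(participants, seq_len(n_items)))
  group_counts <- colMeans(counts)
  if (anyDuplicated(group_counts))
    warning("tied group counts; ranks broken by lower item id")
  ranks <- rank(-group_counts, ties.method = "first")
  labels <- ifelse(ranks <= n_items / 2, "HP", "LP")
  structure(list(counts = counts, group_counts = group_counts,
                 ranks = ranks, labels = labels,
                 n_blocks = length(unique(records$block))),
            class = "preference_profile")
}

#' Inter-subject consistency of choice counts
#'
#' Pearson correlation of the per-item choice-count vectors for every
#' unordered pair of participants, plus a one-sample two-tailed t-test of
#' the coefficients against zero with df = n_pairs - 1. Participants with
#' zero variance in their counts produce undefined correlations; affected
#' pairs are dropped with a warning.
#'
#' @param profile a `preference_profile`.
#' @return list with `r` (vector of pairwise correlations), `r_mean`,
#'   `r_sd`, `t`, `df`, `p`, `n_pairs`, `n_excluded`.
#' @export
intersubject_consistency <- function(profile) {
  counts <- profile$counts
  n <- nrow(counts)
  if (n < 3) stop("need at least 3 participants")
  keep <- apply(counts, 1, stats::sd) > 0
  n_excl_part <- sum(!keep)
  if (n_excl_part > 0)
    warning(n_excl_part, " participant(s) with constant counts excluded ",
            "from inter-subject correlations")
  cm <- stats::cor(t(counts[keep, , drop = FALSE]))
  r <- cm[upper.tri(cm)]
  if (stats::sd(r) == 0) {
    ## all coefficients identical (e.g. identical count profiles)
    t_stat <- if (mean(r) == 0) 0 else sign(mean(r)) * Inf
    return(list(r = r, r_mean = mean(r), r_sd = 0, t = t_stat,
                df = length(r) - 1, p = if (mean(r) == 0) 1 else 0,
                n_pairs = length(r), n_excluded = choose(n, 2) - length(r)))
  }
  tt <- stats::t.test(r, mu = 0)
  list(r = r, r_mean = mean(r), r_sd = stats::sd(r),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_pairs = length(r),
       n_excluded = choose(n, 2) - length(r))
}

#' Within-participant choice-switch consistency
#'
#' For each participant and each item pair, counts transitions between the
#' winners of consecutive blocks. A pair is inconsistent when the
#' participant changed their choice more than twice (strictly greater than
#' 2 transitions) over the block repetitions.
#'
#' @param records choice records with a complete block design.
#' @param n_blocks expected number of blocks (default: the highest block
#'   index present); every participant must have all of them.
#' @return list with `mean` and `sd` of the per-participant inconsistent
#'   pair counts, `fraction` (mean count over the number of pairs), and the
#'   per-participant counts.
#' @export
choice_switch_consistency <- function(records, n_blocks = max(records$block)) {
  participants <- sort(unique(records$participant))
  blocks <- seq_len(n_blocks)
  counts <- vapply(participants, function(p) {
    rp <- records[records$participant == p, ]
    if (!setequal(unique(rp$block), blocks))
      stop("participant ", p, " is missing one or more blocks")
    pair <- paste(pmin(rp$item_a, rp$item_b), pmax(rp$item_a, rp$item_b))
    sum(vapply(split(rp[order(rp$block), ], pair[order(rp$block)]),
               function(d) {
                 w <- d$chosen[order(d$block)]
                 sum(w[-1] != w[-length(w)]) > 2
               }, logical(1)))
  }, numeric(1))
  n_pairs <- length(unique(paste(pmin(records$item_a, records$item_b),
                                 pmax(records$item_a, records$item_b))))
  list(mean = mean(counts), sd = stats::sd(counts),
       fraction = mean(counts) / n_pairs, per_participant = counts)
}

#' Paired t-test of HP versus LP choice counts
#'
#' Per participant, the mean count over HP items against the mean over LP
#' items, compared with a two-tailed paired t-test. Zero variance of the
#' differences is reported as degenerate rather than an infinite statistic.
#'
#' @param profile a `preference_profile` with HP/LP labels.
#' @return list with `t`, `df`, `p`, `mean_hp`, `mean_lp`, `degenerate`.
#' @export
hp_lp_choice_test <- function(profile) {
  counts <- profile$counts
  if (nrow(counts) < 2) stop("need at least 2 participants")
  hp <- rowMeans(counts[, profile$labels == "HP", drop = FALSE])
  lp <- rowMeans(counts[, profile$labels == "LP", drop = FALSE])
  d <- hp - lp
  if (stats::sd(d) == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t_stat, df = length(d) - 1,
                p = if (mean(d) == 0) 1 else 0,
                mean_hp = mean(hp), mean_lp = mean(lp), degenerate = TRUE))
  }
  tt <- stats::t.test(hp, lp, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_hp = mean(hp), mean_lp = mean(lp), degenerate = FALSE)
}

#' Spearman correlation between choice counts and willingness to pay
#'
#' Item-level association between the group mean choice count and the group
#' mean bid.
#'
#' @param profile a `preference_profile`.
#' @param wtp data.frame of bids (`participant`, `item`, `bid`).
#' @return list with `rho`, `p`, `n`, `degenerate` (TRUE when mean bids are
#'   constant, in which case the correlation is undefined).
#' @export
wtp_choice_correlation <- function(profile, wtp) {
  mean_bid <- tapply(wtp$bid, factor(wtp$item,
                                     levels = seq_along(profile$group_counts)),
                     mean)
  if (any(is.na(mean_bid))) stop("every item needs at least one bid")
  if (stats::sd(mean_bid) == 0) {
    warning("constant mean bids; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(mean_bid),
                degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(profile$group_counts,
                                         as.numeric(mean_bid),
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(mean_bid),
       degenerate = FALSE)
}
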