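#' Build the Preference x Anterior-Posterior x Laterality cell matrix
#'
#' Collapses per-electrode component scores into the 18 cells of the
#' 2 (Preference: HP vs LP) x 3 (AP: Anterior, Central, Posterior) x
#' 3 (LAT: Left, Midline, Right) within-subject design, with the standard
#' nine-electrode mapping (F3 Fz F4 / C3 Cz C4 / P3 Pz P4). A cell value is
#' the participant's mean score over the six items of the preference group
#' at that electrode.
#'
#' @param scores data.frame from [electrode_scores()] (participant, item,
#'   channel, value).
#' @param profile a `preference_profile` with HP/LP labels.
#' @return a `cell_matrix`: list with `values`, an array participant x
#'   preference(2) x ap(3) x lat(3).
#' @export
build_cells <- function(scores, profile) {
  electrode_map <- data.frame(
    channel = c("F3", "Fz", "F4", "C3", "Cz", "C4", "P3", "Pz", "P4"),
    ap = rep(c("Anterior", "Central", "Posterior"), each = 3),
    lat = rep(c("Left", "Midline", "Right"), times = 3)
  )
  missing <- setdiff(electrode_map$channel, unique(scores$channel))
  if (length(missing))
    stop("missing electrode score(s): ", paste(missing, collapse = ", "))
  participants <- sort(unique(scores$participant))
  n <- length(participants)
  vals <- array(NA_real_, dim = c(n, 2, 3, 3),
                dimnames = list(NULL, preference = c("HP", "LP"),
                                ap = c("Anterior", "Central", "Posterior"),
                                lat = c("Left", "Midline", "Right")))
  for (g in c("HP", "LP")) {
    items <- which(profile$labels == g)
    sub <- scores[scores$item %in% items, ]
    for (e in seq_len(nrow(electrode_map))) {
      se <- sub[sub$channel == electrode_map$channel[e], ]
      m <- tapply(se$value, factor(se$participant, levels = participants),
                  mean)
      vals[, g, electrode_map$ap[e], electrode_map$lat[e]] <- as.numeric(m)
    }
  }
  if (anyNA(vals)) stop("incomplete cell matrix")
  structure(list(values = vals, participants = participants),
            class = "cell_matrix")
}

## orthonormal Helmert contrasts for a k-level factor (k x (k-1)),
## plus the normalized mean vector as the "not in effect" column
.ortho_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Three-way fully within-subject repeated-measures ANOVA
#'
#' Computes sums of squares for the three main effects, three two-way and
#' the three-way interaction of the Preference x AP x LAT design, each with
#' its own subject-by-effect error term, via orthonormal contrast scores.
#' The Greenhouse-Geisser epsilon is estimated per effect from the
#' covariance of its contrast scores (epsilon = 1 exactly for single-df
#' effects such as the 2-level Preference factor); both uncorrected and
#' GG-corrected p-values are reported, together with partial eta squared.
#'
#' @param cells a `cell_matrix` from [build_cells()].
#' @return data.frame, one row per effect: effect, df1, df2, f_stat,
#'   epsilon, df1_gg, df2_gg, p_uncorrected, p_gg, partial_eta_sq,
#'   ss_effect, ss_error.
#' @export
rm_anova <- function(cells) {
  Y <- matrix(cells$values, nrow = dim(cells$values)[1])
  n <- nrow(Y)
  if (n < 3) stop("need at least 3 participants")
  k <- c(2, 3, 3)                       # factor levels in column-order
  fac_names <- c("Preference", "AP", "LAT")
  effects <- list(c(1), c(2), c(3), c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  total_within <- sum((Y - rowMeans(Y))^2)
  rows <- lapply(effects, function(eff) {
    parts <- lapply(seq_along(k), function(f) {
      if (f %in% eff) .ortho_contrasts(k[f])
      else matrix(rep(1 / sqrt(k[f]), k[f]), ncol = 1)
    })
    ## cell index varies factor 1 fastest -> kron in reverse factor order
    M <- kronecker(kronecker(parts[[3]], parts[[2]]), parts[[1]])
    Z <- Y %*% M
    d <- ncol(M)
    zbar <- colMeans(Z)
    ss_eff <- n * sum(zbar^2)
    Zc <- sweep(Z, 2, zbar)
    ss_err <- sum(Zc^2)
    df1 <- d
    df2 <- d * (n - 1)
    ## an exactly-null effect leaves only floating-point dust in both sums
    ## of squares; report it as truly null instead of a dust ratio
    dust <- 1e-12 * max(total_within, .Machine$double.xmin)
    if (ss_eff < dust && ss_err < dust) ss_eff <- ss_err <- 0
    f_stat <- if (ss_eff == 0) 0 else (ss_eff / df1) / (ss_err / df2)
    if (d == 1) {
      eps <- 1
    } else {
      S <- stats::cov(Z)
      denom <- d * sum(S^2)
      eps <- if (denom > 0) sum(diag(S))^2 / denom else NA_real_
      if (!is.finite(eps)) {
        warning("singular contrast covariance; lower-bound epsilon used")
        eps <- 1 / d
      }
      eps <- min(1, max(1 / d, eps))
    }
    data.frame(
      effect = paste(fac_names[eff], collapse = ":"),
      df1 = df1, df2 = df2, f_stat = f_stat, epsilon = eps,
      df1_gg = eps * df1, df2_gg = eps * df2,
      p_uncorrected = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
      p_gg = stats::pf(f_stat, eps * df1, eps * df2, lower.tail = FALSE),
      partial_eta_sq = if (ss_eff == 0) 0 else ss_eff / (ss_eff + ss_err),
      ss_effect = ss_eff, ss_error = ss_err)
  })
  do.call(rbind, rows)
}

#' Simple effects of Preference at each site
#'
#' At every level of the chosen topographic factor, a 2-level
#' repeated-measures test of Preference (paired t over the HP-minus-LP
#' differences averaged over the remaining factor; F = t^2) with partial
#' eta squared.
#'
#' @param cells a `cell_matrix`.
#' @param by "AP" or "LAT".
#' @return data.frame: level, t, f_stat, df, p, partial_eta_sq, mean_diff.
#' @export
simple_effects <- function(cells, by = c("AP", "LAT")) {
  by <- match.arg(by)
  v <- cells$values                     # n x pref x ap x lat
  levels_by <- dimnames(v)[[if (by == "AP") 3 else 4]]
  rows <- lapply(levels_by, function(lv) {
    slab <- if (by == "AP") v[, , lv, , drop = FALSE]
            else v[, , , lv, drop = FALSE]
    hp <- apply(slab[, "HP", , , drop = FALSE], 1, mean)
    lp <- apply(slab[, "LP", , , drop = FALSE], 1, mean)
    d <- hp - lp
    n <- length(d)
    if (stats::sd(d) == 0) {
      t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
    } else {
      t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
      p <- 2 * stats::pt(abs(t_stat), n - 1, lower.tail = FALSE)
    }
    eta <- if (is.infinite(t_stat)) 1 else t_stat^2 / (t_stat^2 + (n - 1))
    data.frame(level = lv, t = t_stat, f_stat = t_stat^2, df = n - 1,
               p = p, partial_eta_sq = eta, mean_diff = mean(d))
  })
  do.call(rbind, rows)
}

#' Bonferroni correction across the five late-positivity windows
#'
#' The same Preference test is run once per late window (400-800, 800-1200,
#' 1200-1600, 1600-2000, 2000-3000 ms), so each p-value is multiplied by
#' the family size 5 and capped at 1.
#'
#' @param p_values numeric vector of exactly five uncorrected p-values.
#' @return corrected p-values.
#' @export
bonferroni_late_windows <- function(p_values) {
  if (length(p_values) != 5)
    stop("expected exactly 5 late-window p-values, got ", length(p_values))
  pmin(1, 5 * p_values)
}
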