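#' Coefficient sets
#'
#' A coefficient set indexes selection coefficients (and standard errors)
#' by herd, season, strategy, and covariate — the long-format table the
#' consistency analysis consumes. [as_coef_set()] validates the columns
#' and basic invariants (positive SEs where present).
#'
#' @param df data.frame with columns `herd, season, strategy, covariate,
#'   beta` and optionally `se`.
#' @return the validated data.frame, classed `coef_set`.
#' @export
as_coef_set <- function(df) {
  need <- c("herd", "season", "strategy", "covariate", "beta")
  if (!all(need %in% names(df))) {
    stop("coefficient set needs columns: ", paste(need, collapse = ", "))
  }
  if ("se" %in% names(df) && any(!is.na(df$se) & df$se <= 0)) {
    stop("standard errors must be positive")
  }
  if (anyDuplicated(df[, c("herd", "season", "strategy", "covariate")])) {
    stop("duplicate (herd, season, strategy, covariate) entries")
  }
  class(df) <- unique(c("coef_set", class(df)))
  df
}

# herds holding the complete season x strategy x covariate grid (herds
# missing a strategy cannot enter strategy comparisons)
complete_herds <- function(coeffs) {
  herds <- unique(coeffs$herd)
  full <- expand.grid(season = unique(coeffs$season),
                      strategy = unique(coeffs$strategy),
                      covariate = unique(coeffs$covariate),
                      stringsAsFactors = FALSE)
  keep <- vapply(herds, function(h) {
    sub <- coeffs[coeffs$herd == h, ]
    nrow(merge(full, sub[, c("season", "strategy", "covariate")])) ==
      nrow(full)
  }, logical(1))
  herds[keep]
}

#' Consistency score
#'
#' The consistency score quantifies differentiation in selection behavior:
#' the mean, over all unordered pairs of levels of a varying index (herd,
#' season, or strategy) and over the covariates considered, of the
#' absolute difference between selection coefficients. It is always
#' non-negative, zero only for identical coefficient vectors, and
#' translation invariant.
#'
#' @param coeffs a coefficient set ([as_coef_set()]).
#' @param vary which index varies: `"herd"`, `"season"`, or `"strategy"`.
#' @param fixed named list pinning the other indices, e.g.
#'   `list(season = "winter", strategy = "migrant")`.
#' @param subset covariates to include (default: all present).
#' @return the score (numeric scalar).
#' @examples
#' g <- expand.grid(herd = c("A", "B", "C"), season = "winter",
#'                  strategy = "migrant", covariate = "ndvi",
#'                  stringsAsFactors = FALSE)
#' g$beta <- c(1, 2, 4)
#' consistency_score(as_coef_set(g), vary = "herd",
#'                   fixed = list(season = "winter", strategy = "migrant"))
#' # (|1-2| + |1-4| + |2-4|) / 3 = 2
#' @export
consistency_score <- function(coeffs, vary, fixed = list(), subset = NULL) {
  vary <- match.arg(vary, c("herd", "season", "strategy"))
  sub <- coeffs
  for (nm in names(fixed)) sub <- sub[sub[[nm]] %in% fixed[[nm]], ]
  if (!is.null(subset)) sub <- sub[sub$covariate %in% subset, ]
  if (nrow(sub) == 0) stop("no coefficients match the requested indices")
  levels <- unique(coeffs[[vary]])  # full grid: a missing level is a hole
  if (length(levels) < 2) {
    stop("need at least two levels of '", vary, "' to compare")
  }
  ks <- unique(sub$covariate)
  diffs <- c()
  for (a in seq_along(levels)) {
    for (b in seq_along(levels)) {
      if (b <= a) next
      for (k in ks) {
        bi <- sub$beta[sub[[vary]] == levels[a] & sub$covariate == k]
        bj <- sub$beta[sub[[vary]] == levels[b] & sub$covariate == k]
        if (length(bi) != 1 || length(bj) != 1) {
          stop("coefficient grid has a hole at ", vary, " in {",
               levels[a], ",", levels[b], "}, covariate ", k,
               " (fixed: ", paste(unlist(fixed), collapse = "/"), ")")
        }
        diffs <- c(diffs, abs(bi - bj))
      }
    }
  }
  mean(diffs)
}

# Index-pair representation of a grouping score: rows (i, j) into the
# coefficient set and a block id; the score is the unweighted mean over
# blocks of the within-block mean |beta_i - beta_j|.
grouping_pairs <- function(coeffs, grouping, subset = NULL) {
  cs <- coeffs  # indices refer to rows of `coeffs` as passed
  row_of <- function(h, s, m, k) {
    w <- which(cs$herd == h & cs$season == s & cs$strategy == m &
                 cs$covariate == k)
    if (length(w) != 1) {
      stop("coefficient grid has a hole at ", h, "/", s, "/", m, "/", k)
    }
    w
  }
  seasons <- unique(cs$season)
  strategies <- unique(cs$strategy)
  ks <- unique(cs$covariate)
  if (!is.null(subset)) {
    ks <- intersect(ks, subset)
    if (length(ks) == 0) stop("covariate subset matches nothing")
  }

  build <- function(vary_levels, fixed_combos, getter) {
    out <- list()
    blk <- 0
    for (fc in fixed_combos) {
      blk <- blk + 1
      for (a in seq_along(vary_levels)) {
        for (b in seq_along(vary_levels)) {
          if (b <= a) next
          for (k in ks) {
            ij <- getter(vary_levels[a], vary_levels[b], fc, k)
            out[[length(out) + 1]] <- c(ij, blk)
          }
        }
      }
    }
    m <- do.call(rbind, out)
    data.frame(i = m[, 1], j = m[, 2], block = m[, 3])
  }

  if (grouping == "among_herd") {
    herds <- complete_herds(cs)
    if (length(herds) < 2) stop("need two herds with complete grids")
    combos <- apply(expand.grid(seasons, strategies), 1, as.list)
    build(herds, combos, function(a, b, fc, k) {
      c(row_of(a, fc[[1]], fc[[2]], k), row_of(b, fc[[1]], fc[[2]], k))
    })
  } else if (grouping == "between_season") {
    herds <- complete_herds(cs)
    combos <- apply(expand.grid(herds, strategies), 1, as.list)
    build(seasons, combos, function(a, b, fc, k) {
      c(row_of(fc[[1]], a, fc[[2]], k), row_of(fc[[1]], b, fc[[2]], k))
    })
  } else if (grouping == "between_strategy") {
    herds <- complete_herds(cs)
    combos <- apply(expand.grid(herds, seasons), 1, as.list)
    build(strategies, combos, function(a, b, fc, k) {
      c(row_of(fc[[1]], fc[[2]], a, k), row_of(fc[[1]], fc[[2]], b, k))
    })
  } else if (grepl("^season_strategy:", grouping)) {
    s <- sub("^season_strategy:", "", grouping)
    herds <- complete_herds(cs)
    build(strategies, as.list(herds), function(a, b, fc, k) {
      c(row_of(fc, s, a, k), row_of(fc, s, b, k))
    })
  } else if (grepl("^herd:", grouping)) {
    h <- sub("^herd:", "", grouping)
    if (!h %in% complete_herds(cs)) {
      stop("herd ", h, " lacks a complete strategy grid")
    }
    build(strategies, as.list(seasons), function(a, b, fc, k) {
      c(row_of(h, fc, a, k), row_of(h, fc, b, k))
    })
  } else {
    stop("unknown grouping: ", grouping)
  }
}

score_from_pairs <- function(beta, pairs) {
  d <- abs(beta[pairs$i] - beta[pairs$j])
  mean(tapply(d, pairs$block, mean))
}

#' Aggregate consistency scores per grouping
#'
#' Computes the standard grouping scores from a coefficient grid restricted
#' to herds carrying both strategies:
#' \describe{
#'   \item{among_herd}{mean over season-strategy combinations of the
#'     across-herd score — spatial differentiation.}
#'   \item{between_season}{mean over herd-strategy combinations of the
#'     across-season score — temporal differentiation.}
#'   \item{between_strategy}{mean over herd-season combinations of the
#'     migrant-resident score — strategy differentiation.}
#'   \item{season_strategy:winter / :summer}{strategy differentiation per
#'     season, contrasting the sympatric (winter) and allopatric (summer)
#'     periods.}
#'   \item{herd:<name>}{strategy differentiation per herd.}
#' }
#'
#' @param coeffs a coefficient set.
#' @param subset optional covariate subset (e.g. one covariate group).
#' @return named numeric vector of scores.
#' @export
grouping_scores <- function(coeffs, subset = NULL) {
  coeffs <- as_coef_set(coeffs)
  herds_ok <- complete_herds(if (is.null(subset)) coeffs else
    coeffs[coeffs$covariate %in% subset, ])
  dropped <- setdiff(unique(coeffs$herd), herds_ok)
  if (length(dropped)) {
    message("herds without both strategies dropped from comparisons: ",
            paste(dropped, collapse = ", "))
  }
  cs <- coeffs[coeffs$herd %in% herds_ok, ]
  groupings <- c("among_herd", "between_season", "between_strategy",
                 paste0("season_strategy:", unique(cs$season)),
                 paste0("herd:", herds_ok))
  out <- vapply(groupings, function(g) {
    p <- grouping_pairs(cs, g, subset = subset)
    score_from_pairs(cs$beta, p)
  }, numeric(1))
  names(out) <- groupings
  out
}

#' Monte Carlo distribution of a consistency score
#'
#' Propagates coefficient uncertainty into the consistency score: each
#' draw perturbs every coefficient independently as
#' `Normal(beta, se^2)` (models are fit independently per
#' herd-season-strategy, so no cross-covariance is available) and
#' recomputes the grouping score. The resulting draws feed the violin
#' summaries and Dunnett's T3 ranking.
#'
#' @param coeffs coefficient set with positive `se`.
#' @param grouping grouping label (see [grouping_scores()]).
#' @param subset optional covariate subset.
#' @param B number of Monte Carlo draws.
#' @param seed integer seed.
#' @return object of class `consistency_dist`: `draws`, `mean`, `ci`
#'   (2.5/97.5% quantiles), `grouping`, `subset`, `B`, `seed`.
#' @export
mc_distribution <- function(coeffs, grouping, subset = NULL, B = 10000,
                            seed = 1L) {
  coeffs <- as_coef_set(coeffs)
  if (!"se" %in% names(coeffs) || any(is.na(coeffs$se))) {
    stop("Monte Carlo propagation needs standard errors")
  }
  if (B < 100) warning("B < 100 gives unstable intervals")
  cs <- coeffs[coeffs$herd %in% complete_herds(coeffs), ]
  pairs <- grouping_pairs(cs, grouping, subset = subset)
  set.seed(seed)
  n <- nrow(cs)
  draws <- matrix(stats::rnorm(B * n, mean = rep(cs$beta, each = B),
                               sd = rep(cs$se, each = B)), B, n)
  d <- abs(draws[, pairs$i, drop = FALSE] - draws[, pairs$j, drop = FALSE])
  # block means, then mean across blocks (equal weight per block)
  blocks <- sort(unique(pairs$block))
  A <- vapply(blocks, function(b) {
    w <- pairs$block == b
    rowMeans(d[, w, drop = FALSE])
  }, numeric(B))
  vals <- if (length(blocks) == 1) as.numeric(A) else rowMeans(A)
  structure(list(
    draws = vals, mean = mean(vals),
    ci = stats::quantile(vals, c(0.025, 0.975), names = FALSE),
    grouping = grouping, subset = subset, B = B, seed = seed
  ), class = "consistency_dist")
}

#' @export
print.consistency_dist <- function(x, ...) {
  cat("<consistency_dist> ", x$grouping,
      if (!is.null(x$subset)) paste0(" [", paste(x$subset, collapse = ","),
                                     "]"),
      sprintf(": mean %.4f, 95%% CI [%.4f, %.4f], B = %d\n",
              x$mean, x$ci[1], x$ci[2], x$B), sep = "")
  invisible(x)
}

#' @export
plot.consistency_dist <- function(x, ...) {
  graphics::hist(x$draws, breaks = 50, main = x$grouping,
                 xlab = "consistency score", ...)
  graphics::abline(v = x$mean, col = 2, lwd = 2)
  invisible(x)
}

# P(max_i |T_i| <= q) for r independent-numerator t variates sharing one
# chi denominator with nu df (studentized maximum modulus); numeric
# integration over the chi density, normal limit for large nu
psmm <- function(q, r, nu) {
  if (q <= 0) return(0)
  if (nu > 2000) return((2 * stats::pnorm(q) - 1)^r)
  lg <- function(s) {
    log(2) + (nu / 2) * log(nu / 2) - lgamma(nu / 2) +
      (nu - 1) * log(s) - nu * s^2 / 2
  }
  f <- function(s) (2 * stats::pnorm(q * s) - 1)^r * exp(lg(s))
  stats::integrate(f, 0, Inf, rel.tol = 1e-8)$value
}

#' Dunnett's T3 pairwise comparisons
#'
#' All-pairs comparison of consistency-score distributions under unequal
#' variances: each pair gets a Welch-type statistic with
#' Welch-Satterthwaite degrees of freedom, and its p-value from the
#' studentized maximum modulus (SMM) family sized by the number of
#' pairwise comparisons (numeric integration of the SMM distribution;
#' normal limit for large df). Groups are ranked and assigned
#' compact-letter-display letters by insert-and-absorb merging at `alpha`:
#' groups sharing no letter differ significantly.
#'
#' @param dists named list of `consistency_dist` objects or numeric draw
#'   vectors (at least two, each with at least two draws).
#' @param alpha family-wise significance level.
#' @return object of class `t3_test`: `pairs` (data.frame `a, b, diff, t,
#'   df, p`), `letters` (named character, ordered by decreasing mean),
#'   `means`, `alpha`, `method`.
#' @export
dunnett_t3 <- function(dists, alpha = 0.05) {
  draws <- lapply(dists, function(d) {
    if (inherits(d, "consistency_dist")) d$draws else as.numeric(d)
  })
  if (is.null(names(draws)) || any(names(draws) == "")) {
    names(draws) <- paste0("g", seq_along(draws))
  }
  k <- length(draws)
  if (k < 2) stop("need at least two distributions")
  if (any(vapply(draws, length, integer(1)) < 2)) {
    stop("each distribution needs at least two draws")
  }
  m <- vapply(draws, mean, numeric(1))
  v <- vapply(draws, stats::var, numeric(1))
  n <- vapply(draws, length, numeric(1))
  r <- k * (k - 1) / 2
  pair_rows <- list()
  method <- "SMM, numeric integration (normal limit above 2000 df)"
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      s2 <- v[a] / n[a] + v[b] / n[b]
      diff <- m[a] - m[b]
      if (s2 == 0) {
        p <- if (diff == 0) 1 else 0
        tt <- if (diff == 0) 0 else Inf
        df <- Inf
      } else {
        tt <- diff / sqrt(s2)
        df <- s2^2 / ((v[a] / n[a])^2 / (n[a] - 1) +
                        (v[b] / n[b])^2 / (n[b] - 1))
        p <- 1 - psmm(abs(tt), r, df)
      }
      pair_rows[[length(pair_rows) + 1]] <- data.frame(
        a = names(draws)[a], b = names(draws)[b],
        diff = diff, t = tt, df = df, p = min(max(p, 0), 1)
      )
    }
  }
  pairs <- do.call(rbind, pair_rows)

  # compact letter display: maximal runs of mutually non-different groups
  ord <- order(-m)
  sig <- matrix(FALSE, k, k, dimnames = list(names(draws), names(draws)))
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$p[i] < alpha
    sig[pairs$a[i], pairs$b[i]] <- s
    sig[pairs$b[i], pairs$a[i]] <- s
  }
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k &&
           !any(sig[ord[i:(j + 1)], ord[i:(j + 1)]])) {
      j <- j + 1
    }
    runs[[i]] <- ord[i:j]
  }
  # keep maximal runs only
  keep <- rep(TRUE, length(runs))
  for (i in seq_along(runs)) {
    for (j in seq_along(runs)) {
      if (i != j && all(runs[[i]] %in% runs[[j]]) &&
          length(runs[[i]]) < length(runs[[j]])) {
        keep[i] <- FALSE
      }
    }
  }
  runs <- unique(runs[keep])
  letters_out <- stats::setNames(rep("", k), names(draws))
  for (i in seq_along(runs)) {
    lab <- letters[(i - 1) %% 26 + 1]
    for (g in runs[[i]]) {
      letters_out[g] <- paste0(letters_out[g], lab)
    }
  }
  structure(list(
    pairs = pairs, letters = letters_out[ord], means = m[ord],
    alpha = alpha, method = method
  ), class = "t3_test")
}

#' @export
print.t3_test <- function(x, ...) {
  cat("<t3_test> Dunnett T3, alpha = ", x$alpha, "\n", sep = "")
  df <- data.frame(group = names(x$means), mean = x$means,
                   letter = x$letters[names(x$means)])
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Migrant prevalence vs. consistency
#'
#' Pearson correlation (two-sided test) between herd-level consistency
#' scores and the herds' migrant proportions — does the mix of strategies
#' in a herd predict how differentiated its selection behavior is?
#'
#' @param scores herd-level mean consistency scores.
#' @param props migrant proportion per herd (aligned with `scores`).
#' @return list `r`, `p`, `n`.
#' @export
prevalence_correlation <- function(scores, props) {
  if (length(scores) != length(props)) stop("inputs must align")
  if (length(scores) < 3) stop("need at least three herds")
  if (stats::sd(scores) == 0 || stats::sd(props) == 0) {
    stop("correlation undefined for constant input")
  }
  ct <- stats::cor.test(props, scores, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(scores))
}

#' Movement-strategy composition with simultaneous CIs
#'
#' Per-herd proportions of migrant / resident / ambiguous / disperser
#' animal-years with Goodman simultaneous 95% multinomial confidence
#' intervals (chi-square based, Bonferroni-sized across the categories).
#' Excluded animal-years do not enter the composition.
#'
#' @param calls a `strategy_calls` table.
#' @param alpha simultaneous error level.
#' @return data.frame `herd, strategy, n, prop, lower, upper`.
#' @export
strategy_proportions <- function(calls, alpha = 0.05) {
  cats <- c("migrant", "resident", "ambiguous", "disperser")
  rows <- list()
  for (h in unique(calls$herd)) {
    sub <- calls[calls$herd == h & calls$strategy %in% cats, ]
    n <- nrow(sub)
    if (n == 0) next
    x <- vapply(cats, function(cc) sum(sub$strategy == cc), numeric(1))
    A <- stats::qchisq(1 - alpha / length(cats), df = 1)
    lo <- (A + 2 * x - sqrt(A * (A + 4 * x * (n - x) / n))) / (2 * (n + A))
    hi <- (A + 2 * x + sqrt(A * (A + 4 * x * (n - x) / n))) / (2 * (n + A))
    rows[[h]] <- data.frame(
      herd = h, strategy = cats, n = unname(x), prop = unname(x) / n,
      lower = pmax(0, unname(lo)), upper = pmin(1, unname(hi))
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
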