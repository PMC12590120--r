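# Inferential machinery: cluster-based permutation tests, FDR adjustment,
# repeated-measures ANOVA with Greenhouse-Geisser correction, and robust
# one-sided Spearman correlations.

#' Cluster-based permutation test for paired time series
#'
#' Paired t statistics at every time point; contiguous runs whose |t| exceeds
#' the two-sided `cluster_alpha` threshold form clusters with mass = sum of t
#' within the run; the null distribution of the maximum absolute cluster mass
#' is built from per-pair random condition sign-flips, and each observed
#' cluster gets a Monte-Carlo p with the plus-one correction. Two-tailed by
#' default (cluster sign is reported); a one-sided variant matching the
#' "upper 5% exceedance" description is available via `tails = 1`.
#'
#' @param condA,condB subjects (or paired trials) x time matrices.
#' @param time time axis in seconds (defaults to sample index).
#' @param n_perm number of permutations (1000).
#' @param cluster_alpha cluster-defining threshold (0.05).
#' @param alpha cluster-level significance level (0.05).
#' @param tails 2 (default) or 1.
#' @param seed required seed for the permutation draw.
#' @return a `cluster_result`: `t_series`, `threshold`, `clusters`
#'   data.frame (`start_s`, `end_s`, `mass`, `p`, `significant`), `n_perm`,
#'   `seed`.
#' @export
cluster_permutation_test <- function(condA, condB, time = NULL, n_perm = 1000,
                                     cluster_alpha = 0.05, alpha = 0.05,
                                     tails = 2, seed) {
  if (missing(seed)) stop("`seed` is required")
  if (!all(dim(condA) == dim(condB))) stop("condition matrices must match")
  n <- nrow(condA)
  if (n < 2) stop("need at least 2 paired rows")
  if (is.null(time)) time <- seq_len(ncol(condA))
  if (length(time) != ncol(condA)) stop("time axis does not match the data")
  D <- condA - condB
  nt <- ncol(D)
  ss <- colSums(D^2)                     # invariant under sign flips
  tval <- function(mean_d) {
    v <- (ss - n * mean_d^2) / (n - 1)
    v[v < .Machine$double.eps] <- .Machine$double.eps
    mean_d / sqrt(v / n)
  }
  t_obs <- tval(colMeans(D))
  thr <- if (tails == 2) stats::qt(1 - cluster_alpha / 2, n - 1)
         else stats::qt(1 - cluster_alpha, n - 1)

  cluster_masses <- function(tv) {
    out <- list()
    for (sgn in if (tails == 2) c(1, -1) else 1) {
      above <- sgn * tv > thr
      r <- rle(above)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        out[[length(out) + 1L]] <- c(start = starts[j], end = ends[j],
                                     mass = sum(tv[starts[j]:ends[j]]))
      }
    }
    out
  }

  obs <- cluster_masses(t_obs)

  set.seed(seed)
  S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  Mperm <- (S %*% D) / n                 # n_perm x nt permuted means
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    cm <- cluster_masses(tval(Mperm[b, ]))
    null_max[b] <- if (length(cm)) max(abs(vapply(cm, `[[`, 0, "mass"))) else 0
  }

  clusters <- if (length(obs)) {
    df <- do.call(rbind, lapply(obs, function(cl) {
      p <- (1 + sum(null_max >= abs(cl[["mass"]]))) / (n_perm + 1)
      data.frame(start_s = time[cl[["start"]]], end_s = time[cl[["end"]]],
                 mass = cl[["mass"]], p = p)
    }))
    df$significant <- df$p < alpha
    df[order(df$p, -abs(df$mass)), , drop = FALSE]
  } else {
    data.frame(start_s = numeric(0), end_s = numeric(0), mass = numeric(0),
               p = numeric(0), significant = logical(0))
  }
  rownames(clusters) <- NULL
  structure(list(t_series = t_obs, time = time, threshold = thr,
                 clusters = clusters, n_perm = n_perm,
                 cluster_alpha = cluster_alpha, alpha = alpha,
                 tails = tails, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d permutations (seed %d)\n",
              nrow(x$clusters), x$n_perm, x$seed))
  if (nrow(x$clusters)) print(round(x$clusters[1:min(5, nrow(x$clusters)), 1:4], 4))
  invisible(x)
}

#' Export cluster intervals as BED-like text
#'
#' Tab-separated `start_s  end_s  mass  p` rows for downstream tooling.
#' @param res a `cluster_result`.
#' @param path output path.
#' @export
export_clusters_bed <- function(res, path) {
  utils::write.table(res$clusters[, c("start_s", "end_s", "mass", "p")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res$clusters)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values (wraps the standard implementation after range
#' validation); never decreases a p value and never exceeds 1.
#'
#' @param pvals numeric vector in `[0, 1]`.
#' @return adjusted p values.
#' @export
fdr_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

# --- repeated-measures ANOVA ------------------------------------------------

# All nonempty subsets of a character vector, as a list.
all_subsets <- function(x) {
  out <- list()
  for (k in seq_along(x)) out <- c(out, utils::combn(x, k, simplify = FALSE))
  out
}

# Mean of y within cells of `by` (named list of factors), broadcast back to
# observation length.
broadcast_mean <- function(y, by) {
  if (!length(by)) return(rep(mean(y), length(y)))
  key <- interaction(as.data.frame(by), drop = TRUE)
  stats::ave(y, key)
}

#' Repeated-measures ANOVA for balanced fully-within designs
#'
#' Textbook sums-of-squares decomposition via Möbius inversion on cell means:
#' for every within-subject effect E the error stratum is the E x subject
#' interaction, and F = MS_E / MS_(E x subject). Supports 1-, 2- and 3-way
#' designs with a complete balanced subject x cell table.
#' Greenhouse-Geisser epsilon is estimated per effect from the sample
#' covariance of the within-subject cell scores (orthonormal contrast form),
#' clipped into `[1/df_effect, 1]`, and applied to effects with more than one
#' numerator df; `p_gg` then uses the corrected df.
#'
#' @param data long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param subject name of the subject identifier column.
#' @param within character vector of within-subject factor columns (1 to 3).
#' @return an `anova_result` data.frame: one row per effect with `effect`,
#'   `df1`, `df2`, `SS`, `SS_error`, `F`, `p`, `epsilon`, `df1_gg`, `df2_gg`,
#'   `p_gg`.
#' @export
rm_anova <- function(data, dv, subject, within) {
  stopifnot(length(within) >= 1, length(within) <= 3)
  y <- data[[dv]]
  subj <- factor(data[[subject]])
  fac <- lapply(within, function(w) factor(data[[w]]))
  names(fac) <- within
  # balance check: every subject x cell combination exactly once
  key <- interaction(c(list(subj), fac), drop = FALSE)
  if (!all(table(key) == 1)) stop("design must be complete and balanced")

  n_subj <- nlevels(subj)
  k_lev <- vapply(fac, nlevels, 0L)
  N <- length(y)

  # Möbius effect decomposition over subsets of {subject, factors}
  units <- c(list(subject = subj), fac)
  effect_term <- function(set) {
    idx <- all_subsets(set)
    term <- rep((-1)^length(set) * mean(y), length(y))  # empty-set term
    for (s in idx) {
      sgn <- (-1)^(length(set) - length(s))
      term <- term + sgn * broadcast_mean(y, units[s])
    }
    term
  }

  rows <- lapply(all_subsets(within), function(eff) {
    e_eff <- effect_term(eff)
    e_err <- effect_term(c("subject", eff))
    SS <- sum(e_eff^2)
    SSe <- sum(e_err^2)
    df1 <- prod(k_lev[eff] - 1L)
    df2 <- df1 * (n_subj - 1L)
    Fv <- (SS / df1) / (SSe / df2)
    eps <- gg_epsilon(y, subj, fac, eff)
    df1g <- eps * df1
    df2g <- eps * df2
    data.frame(effect = paste(eff, collapse = ":"), df1 = df1, df2 = df2,
               SS = SS, SS_error = SSe, F = Fv,
               p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
               epsilon = eps, df1_gg = df1g, df2_gg = df2g,
               p_gg = stats::pf(Fv, df1g, df2g, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("anova_result", class(out))
  out
}

# Greenhouse-Geisser epsilon for effect `eff`: collapse the subject x cell
# table over the remaining factors, apply orthonormal effect contrasts
# (Kronecker product over the effect's factors), epsilon from the contrast
# covariance. Effects with a single df have epsilon 1 by construction.
gg_epsilon <- function(y, subj, fac, eff) {
  df1 <- prod(vapply(fac[eff], nlevels, 0L) - 1L)
  if (df1 <= 1) return(1)
  cells <- interaction(as.data.frame(fac[eff]), drop = FALSE)
  tab <- tapply(y, list(subj, cells), mean)      # subjects x cells-of-effect
  Cm <- Reduce(kronecker, lapply(rev(eff), function(f) {
    k <- nlevels(fac[[f]])
    qr.Q(qr(cbind(rep(1, k), stats::contr.helmert(k))))[, -1, drop = FALSE]
  }))
  # column order of `cells` varies the first factor fastest; kronecker above
  # is built in reversed factor order to match interaction()'s ordering
  S <- stats::cov(tab)
  M <- t(Cm) %*% S %*% Cm
  eps <- sum(diag(M))^2 / (df1 * sum(M^2))
  min(1, max(1 / df1, eps))
}

#' @export
print.anova_result <- function(x, ...) {
  df <- as.data.frame(x)
  class(df) <- "data.frame"
  num <- intersect(c("SS", "SS_error", "F", "p", "epsilon", "p_gg"), names(df))
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  show <- intersect(c("effect", "df1", "df2", "F", "p", "epsilon", "p_gg"),
                    names(df))
  print(df[, show], row.names = FALSE)
  invisible(x)
}

# --- robust correlation -----------------------------------------------------

# Rousseeuw-Croux Sn robust scale (O(n^2), fine for the sample sizes used).
sn_scale <- function(x) {
  n <- length(x)
  med_j <- vapply(seq_len(n), function(i) stats::median(abs(x[i] - x[-i])), 0)
  1.1926 * stats::median(med_j)
}

# Per-method univariate outlier flags, applied to both coordinates: a point
# is flagged by a method if either coordinate is an outlier under its rule.
outlier_flags <- function(x, y) {
  box <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.75))
    iqr <- q[2] - q[1]
    v < q[1] - 1.5 * iqr | v > q[2] + 1.5 * iqr
  }
  madr <- function(v) {
    m <- stats::mad(v)
    if (m == 0) return(rep(FALSE, length(v)))
    abs(v - stats::median(v)) / m > 2.24
  }
  snr <- function(v) {
    s <- sn_scale(v)
    if (s == 0) return(rep(FALSE, length(v)))
    abs(v - stats::median(v)) / s > 2.24
  }
  list(boxplot = box(x) | box(y),
       mad = madr(x) | madr(y),
       s_outlier = snr(x) | snr(y))
}

#' Robust Spearman correlation with triple-method outlier rejection
#'
#' Flags bivariate outliers by the boxplot rule (1.5 IQR whiskers), the
#' median-absolute-deviation rule (cutoff 2.24) and the S-outlier rule (Sn
#' robust scale, cutoff 2.24); only points flagged by all three methods are
#' removed. Spearman's rho with average ranks for ties; one-sided p in the
#' declared direction when `sided = "one"`.
#'
#' @param x,y numeric vectors.
#' @param sided `"one"` or `"two"`.
#' @param direction `"negative"` or `"positive"` expected association
#'   (used when `sided = "one"`).
#' @return a `robust_correlation`: `rho`, `p`, `n_used`, `outliers`
#'   (indices removed), `flags` (per-method logical vectors), `sided`,
#'   `direction`.
#' @export
robust_spearman <- function(x, y, sided = c("one", "two"),
                            direction = c("negative", "positive")) {
  sided <- match.arg(sided)
  direction <- match.arg(direction)
  stopifnot(length(x) == length(y))
  flags <- outlier_flags(x, y)
  out_idx <- which(flags$boxplot & flags$mad & flags$s_outlier)
  keep <- setdiff(seq_along(x), out_idx)
  if (length(keep) < 5) stop("fewer than 5 points after outlier removal")
  alt <- if (sided == "two") "two.sided"
         else if (direction == "negative") "less" else "greater"
  ct <- suppressWarnings(stats::cor.test(x[keep], y[keep], method = "spearman",
                                         alternative = alt, exact = FALSE))
  structure(list(rho = unname(ct$estimate), p = ct$p.value,
                 n_used = length(keep), outliers = out_idx, flags = flags,
                 sided = sided, direction = direction),
            class = "robust_correlation")
}

#' @export
print.robust_correlation <- function(x, ...) {
  cat(sprintf("<robust_correlation> rho = %.3f, p = %.4g (%s-sided %s), n = %d, outliers removed = %d\n",
              x$rho, x$p, x$sided,
              if (x$sided == "one") x$direction else "", x$n_used,
              length(x$outliers)))
  invisible(x)
}
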