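# SAM-style moderated statistic with permutation FDR, two-class unpaired.

# Resolve the two-group factor: returns list(case_idx, ctrl_idx). The
# second level (or "HS" if present) is the case group.
.sam_groups <- function(groups, n_cols) {
  groups <- as.character(groups)
  if (length(groups) != n_cols)
    stop("'groups' length must match the number of samples", call. = FALSE)
  lev <- sort(unique(groups))   # first level in sort order = reference
  if (length(lev) != 2)
    stop("exactly two groups are required", call. = FALSE)
  ctrl <- which(groups == lev[1])
  case <- which(groups == lev[2])
  if (length(ctrl) < 2 || length(case) < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  list(case = case, ctrl = ctrl, levels = lev)
}

# d and pooled SE for all genes at once; x is genes x samples.
.sam_d <- function(x, case, ctrl, s0) {
  n1 <- length(case); n2 <- length(ctrl)
  m1 <- rowMeans(x[, case, drop = FALSE])
  m2 <- rowMeans(x[, ctrl, drop = FALSE])
  ss1 <- rowSums((x[, case, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, ctrl, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(d = (m1 - m2) / (s + s0), s = s)
}

#' SAM d statistic
#'
#' The moderated two-sample statistic
#' \deqn{d_i = (\bar x_{case,i} - \bar x_{ctrl,i}) / (s_i + s_0),}
#' where \eqn{s_i} is the equal-variance pooled standard error and
#' \eqn{s_0} a fudge factor stabilizing genes with tiny variance. With
#' `s0 = 0` this is exactly the equal-variance two-sample t statistic.
#'
#' @param expr Genes x samples numeric matrix.
#' @param groups Character/factor of length `ncol(expr)` with two
#'   levels; the first level in sort order is the reference, so with
#'   CTRL/HS labels the difference is HS minus CTRL.
#' @param s0 Non-negative fudge factor.
#' @return data.frame with columns `gene`, `d`, `s`.
#' @export
sam_statistic <- function(expr, groups, s0 = 0) {
  g <- .sam_groups(groups, ncol(expr))
  res <- .sam_d(expr, g$case, g$ctrl, s0)
  data.frame(gene = rownames(expr), d = res$d, s = res$s,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Choose the SAM fudge factor s0
#'
#' Tusher's coefficient-of-variation criterion: candidate values are the
#' 0, 5, ..., 100 percentiles of the pooled standard errors; for each
#' candidate the genes are split into quantile windows of s and the
#' candidate minimizing the coefficient of variation of the windowed
#' median absolute deviations of d is selected.
#'
#' @inheritParams sam_statistic
#' @param n_windows Number of quantile windows of s (default 10).
#' @return The selected s0 (one of the candidate percentiles). If all
#'   pooled standard errors are equal, 0 with a warning.
#' @export
choose_s0 <- function(expr, groups, n_windows = 10) {
  if (nrow(expr) < 50)
    stop("s0 selection needs at least 50 genes", call. = FALSE)
  g <- .sam_groups(groups, ncol(expr))
  s <- .sam_d(expr, g$case, g$ctrl, 0)$s
  if (diff(range(s)) < .Machine$double.eps^0.5) {
    warning("all pooled standard errors equal; s0 = 0")
    return(0)
  }
  candidates <- unique(quantile(s, seq(0, 1, by = 0.05), names = FALSE))
  win <- cut(rank(s, ties.method = "first"), breaks = n_windows,
             labels = FALSE)
  cv <- vapply(candidates, function(s0) {
    d <- .sam_d(expr, g$case, g$ctrl, s0)$d
    mads <- tapply(d, win, mad)
    sd(mads) / mean(mads)
  }, numeric(1))
  candidates[which.min(cv)]
}

#' SAM permutation analysis with FDR-controlled gene calling
#'
#' Computes d statistics, their expected order statistics under `B`
#' random group-label permutations, and for a grid of thresholds
#' \eqn{\delta} the permutation-estimated FDR; the smallest \eqn{\delta}
#' whose estimated FDR is at or below `target_fdr` defines the called
#' gene set.
#'
#' A gene at sorted position i is called at threshold \eqn{\delta} when
#' \eqn{|d_{(i)} - \bar d_{(i)}| > \delta}. The FDR estimate at
#' \eqn{\delta} is \eqn{\hat\pi_0 \cdot
#' \mathrm{median}_b \#\{d^{perm}_b \textrm{ beyond the calling cutoffs}\}
#' / \#called}, with \eqn{\hat\pi_0 = \min(1, 2\,\hat p)} where
#' \eqn{\hat p} is the fraction of observed d inside the interquartile
#' band of the permuted d. The FDR curve is monotonized to be
#' non-increasing in \eqn{\delta} before selection.
#'
#' @inheritParams sam_statistic
#' @param B Number of label permutations (>= 50).
#' @param target_fdr Target false discovery rate in (0, 1).
#' @param s0 Fudge factor; `NULL` (default) selects it via [choose_s0()].
#' @param n_delta Size of the evenly spaced delta grid.
#' @param seed Integer seed for the permutations.
#' @return An object of class `sam_result`: list with `stats` (data.frame
#'   gene, d, s, called, direction), `s0`, `B`, `pi0`, `delta_table`
#'   (delta, n_called, fdr), `selected_delta` (NA if no delta reaches the
#'   target), `estimated_fdr` at the selected delta, and `dbar` (expected
#'   order statistics).
#' @export
sam_permutation_fdr <- function(expr, groups, B = 200, target_fdr = 0.10,
                                s0 = NULL, n_delta = 50, seed = 1L) {
  if (B < 50) stop("'B' must be at least 50", call. = FALSE)
  if (target_fdr <= 0 || target_fdr >= 1)
    stop("'target_fdr' must be in (0, 1)", call. = FALSE)
  g <- .sam_groups(groups, ncol(expr))
  if (is.null(s0)) s0 <- choose_s0(expr, groups)

  obs <- .sam_d(expr, g$case, g$ctrl, s0)
  n <- nrow(expr)
  ord <- order(obs$d)
  d_sorted <- obs$d[ord]

  set.seed(seed)
  n_samp <- ncol(expr)
  n_case <- length(g$case)
  perm_sorted <- matrix(0, n, B)
  perm_all <- matrix(0, n, B)
  for (b in seq_len(B)) {
    idx <- sample(n_samp, n_case)
    pd <- .sam_d(expr, idx, setdiff(seq_len(n_samp), idx), s0)$d
    perm_all[, b] <- pd
    perm_sorted[, b] <- sort(pd)
  }
  dbar <- rowMeans(perm_sorted)
  diff_stat <- d_sorted - dbar

  q <- quantile(perm_all, c(0.25, 0.75))
  pi0 <- min(1, 2 * mean(obs$d >= q[1] & obs$d <= q[2]))

  max_diff <- max(abs(diff_stat))
  deltas <- seq(max_diff / n_delta, max_diff, length.out = n_delta)
  fdr <- numeric(n_delta)
  n_called <- integer(n_delta)
  for (i in seq_len(n_delta)) {
    delta <- deltas[i]
    up <- diff_stat > delta
    down <- diff_stat < -delta
    n_called[i] <- sum(up) + sum(down)
    if (n_called[i] == 0) { fdr[i] <- 0; next }
    cut_up <- if (any(up)) min(d_sorted[up]) else Inf
    cut_down <- if (any(down)) max(d_sorted[down]) else -Inf
    false_per_perm <- colSums(perm_all >= cut_up) +
      colSums(perm_all <= cut_down)
    fdr[i] <- min(1, pi0 * median(false_per_perm) / n_called[i])
  }
  # monotonize: FDR non-increasing as delta grows. Each delta is assigned
  # the largest raw estimate at that or any larger delta, so a noisy dip
  # at a loose threshold can never masquerade as a strict one.
  fdr <- rev(cummax(rev(fdr)))

  ok <- which(fdr <= target_fdr & n_called > 0)
  called <- logical(n)
  if (length(ok)) {
    sel <- ok[1]
    selected_delta <- deltas[sel]
    estimated_fdr <- fdr[sel]
    called_sorted <- abs(diff_stat) > selected_delta
    called[ord] <- called_sorted
  } else {
    selected_delta <- NA_real_
    estimated_fdr <- NA_real_
  }

  stats <- data.frame(
    gene = rownames(expr), d = obs$d, s = obs$s,
    called = called,
    direction = ifelse(obs$d > 0, "up", "down"),
    row.names = NULL, stringsAsFactors = FALSE)
  stats$direction[!called] <- NA_character_

  structure(list(
    stats = stats, s0 = s0, B = B, pi0 = pi0,
    delta_table = data.frame(delta = deltas, n_called = n_called,
                             fdr = fdr),
    selected_delta = selected_delta,
    estimated_fdr = estimated_fdr,
    dbar = dbar,
    case_level = g$levels[2]
  ), class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat("SAM permutation analysis (", x$B, " permutations, s0 = ",
      signif(x$s0, 3), ", pi0 = ", signif(x$pi0, 3), ")\n", sep = "")
  if (is.na(x$selected_delta)) {
    cat("no delta reached the FDR target; no genes called\n")
  } else {
    cat(sum(x$stats$called), " genes called at delta = ",
        signif(x$selected_delta, 3), " (estimated FDR ",
        signif(100 * x$estimated_fdr, 3), "%)\n", sep = "")
  }
  invisible(x)
}
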